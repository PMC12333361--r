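#' Atomic charge table for the two redox states of a molecule
#'
#' Holds partial charges of the N-electron (neutral) and (N-1)-electron
#' (radical cation) states, from any population scheme (Hirshfeld by
#' default in this field; the arithmetic is scheme-agnostic). The
#' invariant sum(q(N-1)) - sum(q(N)) = +1 (one electron removed) is
#' enforced to 1e-6 e.
#'
#' @param molecule_id Molecule identifier.
#' @param atom_ids Ordered atom identifiers.
#' @param charges_n,charges_nm1 Partial charges (e) of the N and N-1
#'   electron states, aligned with `atom_ids`.
#' @param site_map data.frame with columns `site_id`, `heavy_atom_id`
#'   mapping each proton site to the heavy atom bearing it.
#' @param hydrogen_map Optional data.frame with columns `atom_id`,
#'   `heavy_atom_id`: hydrogens whose charges are folded into their bonded
#'   heavy atom before differencing (standard condensed-Fukui practice).
#' @return A `charge_table` list.
#' @export
charge_table <- function(molecule_id, atom_ids, charges_n, charges_nm1,
                         site_map, hydrogen_map = NULL) {
  stopifnot(length(atom_ids) == length(charges_n),
            length(atom_ids) == length(charges_nm1))
  if (abs((sum(charges_nm1) - sum(charges_n)) - 1) > 1e-6) {
    stop("charge table invariant violated: total charge difference must be ",
         "+1 e (one electron removed)")
  }
  site_map <- as.data.frame(site_map, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "heavy_atom_id") %in% names(site_map)))
  structure(list(molecule_id = molecule_id,
                 atom_ids = as.character(atom_ids),
                 charges_n = as.numeric(charges_n),
                 charges_nm1 = as.numeric(charges_nm1),
                 site_map = site_map, hydrogen_map = hydrogen_map),
            class = "charge_table")
}

#' Condensed nucleophilic Fukui index per proton site
#'
#' The nucleophilic Fukui index f- describes the per-atom electron density
#' change upon removal of one electron and localizes where the radical
#' hole sits: f-_k = q_k(N-1) - q_k(N). Hydrogen charges (if a hydrogen
#' map is present) are folded into their bonded heavy atoms before
#' differencing, and each proton site inherits the value of the heavy atom
#' bearing it. Over all atoms the indices sum to exactly one electron.
#'
#' @param charges A [charge_table()].
#' @return Named numeric vector: f- per `site_id`. The full per-atom
#'   vector is attached as attribute `per_atom`.
#' @examples
#' ct <- charge_table("m", c("C1", "C2"), c(0, 0), c(1, 0),
#'                    data.frame(site_id = "1", heavy_atom_id = "C1"))
#' condensed_fukui(ct)
#' @export
condensed_fukui <- function(charges) {
  stopifnot(inherits(charges, "charge_table"))
  ids <- charges$atom_ids
  qn <- charges$charges_n
  qm <- charges$charges_nm1
  if (!is.null(charges$hydrogen_map)) {
    hm <- charges$hydrogen_map
    if (!all(hm$atom_id %in% ids) || !all(hm$heavy_atom_id %in% ids)) {
      stop("mapping error: hydrogen_map references unknown atom")
    }
    for (i in seq_len(nrow(hm))) {
      h <- match(hm$atom_id[i], ids)
      heavy <- match(hm$heavy_atom_id[i], ids)
      qn[heavy] <- qn[heavy] + qn[h]
      qm[heavy] <- qm[heavy] + qm[h]
      qn[h] <- qm[h] <- 0
    }
    keep <- !ids %in% hm$atom_id
    ids <- ids[keep]; qn <- qn[keep]; qm <- qm[keep]
  }
  f <- qm - qn
  names(f) <- ids
  if (!all(charges$site_map$heavy_atom_id %in% ids)) {
    stop("mapping error: site_map references unknown atom")
  }
  out <- f[charges$site_map$heavy_atom_id]
  names(out) <- charges$site_map$site_id
  attr(out, "per_atom") <- f
  out
}

#' Geminate polarization probability Q
#'
#' The field- and coupling-dependent part of the geminate polarization of
#' a spin-correlated radical pair:
#' Q = (1/12) |a_iso|^2 |g_D - g_M| (mu_B / hbar) B0,
#' with a_iso converted from MHz to angular frequency. Q is quadratic in
#' a_iso and linear in both the g-factor difference and the field. The
#' radical-pair lifetime terms (contact distance, diffusion) are omitted,
#' assuming rapid diffusion beyond the exchange region.
#'
#' @param a_iso Isotropic hyperfine coupling, MHz (signed; only the
#'   magnitude enters Q).
#' @param g_dye,g_mol Electron g-factors of dye and target radicals.
#' @param b0 Magnetic field, Tesla; must be > 0.
#' @param constants Physical constants, see [physical_constants()].
#' @return Q in rad^3 s^-3 (vectorized over the inputs).
#' @examples
#' geminate_polarization_q(1, 2.003, 2.002, 14.1)
#' @export
geminate_polarization_q <- function(a_iso, g_dye, g_mol, b0,
                                    constants = physical_constants()) {
  if (any(b0 <= 0)) stop("domain error: b0 must be positive")
  a_rad <- abs(a_iso) * constants$mhz_to_rad_s
  (1 / 12) * a_rad^2 * abs(g_dye - g_mol) * constants$mu_B_over_hbar * b0
}

#' LUMO(dye) - HOMO(target) energy gap
#'
#' The energy difference between the LUMO of the dye and the HOMO of the
#' target molecule, the frontier-orbital gap relevant for the
#' electron-transfer step of radical-pair formation.
#'
#' @param e_homo_target HOMO energy of the target molecule, eV.
#' @param e_lumo_dye LUMO energy of the dye, eV.
#' @return Gap in eV (vectorized).
#' @export
lumo_homo_gap <- function(e_homo_target, e_lumo_dye) {
  stopifnot(all(is.finite(e_homo_target)), all(is.finite(e_lumo_dye)))
  e_lumo_dye - e_homo_target
}

#' Octanol-water partition coefficient (logP)
#'
#' A supplied value passes through unchanged. Otherwise logP is estimated
#' from a SMILES string by the Wildman-Crippen atom-contribution scheme
#' (via ChemmineOB/Open Babel) and flagged as estimated.
#'
#' @param smiles Optional SMILES string of the molecule.
#' @param supplied Optional known logP value; takes precedence.
#' @return Numeric logP with attribute `source` = "supplied" or
#'   "estimated".
#' @export
estimate_log_p <- function(smiles = NULL, supplied = NULL) {
  if (!is.null(supplied)) {
    return(structure(as.numeric(supplied), source = "supplied"))
  }
  if (is.null(smiles)) {
    stop("missing-feature error: neither a structure nor a value supplied")
  }
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is required for structure-based logP estimation")
  }
  props <- ChemmineOB::prop_OB(
    ChemmineOB::forEachMol("SMILES", smiles, identity))
  structure(as.numeric(props$logP), source = "estimated")
}

#' Assemble the eight-feature per-site table
#'
#' Builds one row per proton site with the eight molecular features: IP,
#' nucleophilicity N, LUMO-HOMO gap, |Delta g|, a_iso, Fukui f-, Q, and
#' logP. Delta g and Q are computed from the mechanism-selected radical
#' parameters of each molecule; Q is stored divided by `config$q_scale`
#' for numeric conditioning (the scale is table metadata).
#'
#' @param molecules List of [molecule_record()]s, each mechanism-resolved
#'   (a single radical parameter set installed; see
#'   [select_radical_features()]).
#' @param config A [pipeline_config()] supplying the dye g-factor, dye
#'   LUMO energy, field and Q scale.
#' @return A [feature_table()].
#' @export
assemble_features <- function(molecules, config = pipeline_config()) {
  rows <- lapply(molecules, function(m) {
    stopifnot(inherits(m, "molecule_record"))
    if (identical(m$mechanism, "ambiguous")) {
      stop("ambiguity error: molecule ", m$molecule_id,
           " has an unresolved mechanism; run assign_mechanism / ",
           "select_radical_features first")
    }
    s <- m$sites
    dg <- abs(config$g_dye - m$g_mol)
    q <- geminate_polarization_q(s$a_iso, config$g_dye, m$g_mol,
                                 config$b0) / config$q_scale
    out <- data.frame(
      molecule_id = m$molecule_id, family = m$family, series = m$series,
      site_id = as.character(s$site_id),
      ip = m$ip, nucleophilicity = m$nucleophilicity,
      lumo_homo = lumo_homo_gap(m$e_homo, config$e_lumo_dye),
      delta_g = dg, a_iso = s$a_iso, fukui = s$fukui, q_value = q,
      log_p = m$log_p, sne = s$sne, mechanism = m$mechanism,
      stringsAsFactors = FALSE)
    for (cn in c("hirshfeld_charge", "spin_density")) {
      if (cn %in% names(s)) out[[cn]] <- s[[cn]]
    }
    out
  })
  feature_table(do.call(rbind, rows), q_scale = config$q_scale)
}
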
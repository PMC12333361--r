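#' @keywords internal
"_PACKAGE"

# Internal column vocabulary. The CSV schema carries units in the header
# (ip_eV, a_iso_MHz); internally the unit suffixes are dropped once.
.feature_names <- c("ip", "nucleophilicity", "lumo_homo", "delta_g",
                    "a_iso", "fukui", "q_value", "log_p")
.id_cols <- c("molecule_id", "family", "series", "site_id")
.required_cols <- c(.id_cols, .feature_names, "sne")
.optional_cols <- c("hirshfeld_charge", "spin_density", "mechanism")
.csv_names <- c(molecule_id = "molecule_id", family = "family",
                series = "series", site_id = "site_id",
                ip = "ip_eV", nucleophilicity = "nucleophilicity_eV",
                lumo_homo = "lumo_homo_eV", delta_g = "delta_g",
                a_iso = "a_iso_MHz", fukui = "fukui", q_value = "q_value",
                log_p = "log_p", sne = "sne",
                hirshfeld_charge = "hirshfeld_charge",
                spin_density = "spin_density", mechanism = "mechanism")
.families <- c("indole", "amino_acid", "phenol")

#' Names of the eight molecular feature columns
#'
#' Order used throughout the package: ionization potential, nucleophilicity
#' index, LUMO(dye)-HOMO(target) gap, |Delta g|, isotropic hyperfine
#' coupling, nucleophilic Fukui index, geminate polarization probability Q,
#' and logP.
#'
#' @return Character vector of length 8.
#' @export
feature_names <- function() .feature_names

#' Construct a validated per-site feature table
#'
#' The feature table is the central analysis object: one row per
#' (molecule, proton site) carrying the eight molecular features and the
#' observed absolute signal-to-noise enhancement (SNE). Molecule-level
#' features (IP, N, gap, Delta g, logP) are repeated across the sites of a
#' molecule.
#'
#' @param df A data.frame with at least the required columns:
#'   `molecule_id, family, series, site_id`, the eight features (internal
#'   names, see [feature_names()]) and `sne`. Optional columns:
#'   `hirshfeld_charge`, `spin_density`, `mechanism`.
#' @param q_scale Scale constant by which stored `q_value` has been divided
#'   (recorded as metadata; default 1e21).
#' @return A `feature_table` (data.frame subclass) with attributes
#'   `feature_names` and `q_scale`.
#' @export
feature_table <- function(df, q_scale = 1e21) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(.required_cols, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(df$molecule_id, df$site_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("integrity error: duplicate (molecule_id, site_id): ",
         paste(gsub("\r", "/", dup), collapse = ", "))
  }
  num_cols <- c(.feature_names, "sne",
                intersect(c("hirshfeld_charge", "spin_density"), names(df)))
  for (cn in num_cols) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in .id_cols) df[[cn]] <- as.character(df[[cn]])
  keep <- c(.required_cols, intersect(.optional_cols, names(df)))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("feature_table", "data.frame"),
            feature_names = .feature_names, q_scale = q_scale)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d sites, %d molecules, %d families\n",
              nrow(x), length(unique(x$molecule_id)),
              length(unique(x$family))))
  NextMethod()
}

#' Load a per-site feature table from CSV
#'
#' Reads the documented CSV schema (UTF-8, header row, "." decimal
#' separator): `molecule_id,family,series,site_id,ip_eV,nucleophilicity_eV,
#' lumo_homo_eV,delta_g,a_iso_MHz,fukui,q_value,log_p,sne` plus optional
#' `hirshfeld_charge,spin_density,mechanism`. Rows with any missing
#' required field are rejected and reported.
#'
#' @param path Path to the CSV file.
#' @param config A [pipeline_config()]; supplies the `q_value` scale
#'   metadata.
#' @return A validated [feature_table()]. The attribute `rejected_rows`
#'   lists 1-based row numbers dropped for missing required fields.
#' @export
load_feature_table <- function(path, config = pipeline_config()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, encoding = "UTF-8")
  missing <- setdiff(unname(.csv_names[.required_cols]), names(raw))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  present <- .csv_names[.csv_names %in% names(raw)]
  df <- raw[, unname(present), drop = FALSE]
  names(df) <- names(present)
  req_num <- c(.feature_names, "sne")
  for (cn in req_num) df[[cn]] <- as.numeric(df[[cn]])
  bad <- which(Reduce(`|`, lapply(df[.required_cols], function(v) {
    is.na(v) | (is.character(v) & !nzchar(v))
  })))
  if (length(bad)) {
    warning("rejected ", length(bad), " row(s) with missing required fields: ",
            paste(utils::head(bad, 20), collapse = ", "))
    df <- df[-bad, , drop = FALSE]
  }
  tb <- feature_table(df, q_scale = config$q_scale)
  attr(tb, "rejected_rows") <- if (length(bad)) bad else integer(0)
  tb
}

#' Write a feature table to CSV in the documented schema
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  nm <- .csv_names[names(df)]
  names(df) <- unname(nm)
  # 17 significant digits: doubles survive the write -> read round trip
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a feature table against the dataset invariants
#'
#' Report-only checker for the invariants the analysis relies on:
#' non-negative SNE and Q, finite Fukui indices and features, unique
#' (molecule, site) keys, known families, and at least one site per
#' molecule. Validation never mutates the table and is idempotent.
#'
#' @param table A [feature_table()] (or coercible data.frame).
#' @return A `validation_report`: list with `n_rows`, `n_molecules`,
#'   `n_sites_per_molecule`, `violations` (data.frame of row, column,
#'   message) and `clean` flag.
#' @export
validate_dataset <- function(table) {
  df <- as.data.frame(table)
  v <- list()
  note <- function(rows, col, msg) {
    if (length(rows)) {
      v[[length(v) + 1L]] <<- data.frame(row = rows, column = col,
                                         message = msg,
                                         stringsAsFactors = FALSE)
    }
  }
  note(which(df$sne < 0), "sne", "sne must be >= 0")
  note(which(df$q_value < 0), "q_value", "q_value must be >= 0")
  for (cn in .feature_names) {
    note(which(!is.finite(df[[cn]])), cn, "feature must be finite")
  }
  note(which(df$delta_g < 0), "delta_g", "delta_g must be >= 0")
  note(which(!df$family %in% .families), "family",
       paste("family must be one of:", paste(.families, collapse = ", ")))
  key <- paste(df$molecule_id, df$site_id, sep = "\r")
  note(which(duplicated(key)), "site_id",
       "duplicate (molecule_id, site_id)")
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(row = integer(0), column = character(0),
               message = character(0), stringsAsFactors = FALSE)
  structure(list(
    n_rows = nrow(df),
    n_molecules = length(unique(df$molecule_id)),
    n_sites_per_molecule = table(df$molecule_id),
    violations = violations,
    clean = nrow(violations) == 0L
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d rows, %d molecules, %s\n",
              x$n_rows, x$n_molecules,
              if (x$clean) "clean" else
                sprintf("%d violation(s)", nrow(x$violations))))
  if (!x$clean) print(utils::head(x$violations, 10))
  invisible(x)
}

#' Assemble a molecule record
#'
#' Bundles the molecule-level features with its per-site records. Used as
#' the input unit of [assemble_features()] and of the mechanism stage.
#'
#' @param molecule_id,family,series Identifiers; `family` must be one of
#'   indole, amino_acid, phenol.
#' @param ip,nucleophilicity,e_homo,log_p Molecule-level features (eV, eV,
#'   eV, dimensionless). The LUMO-HOMO gap is formed against the dye LUMO
#'   at assembly time from `e_homo`.
#' @param g_mol Molecule radical g-factor (used for Delta g and Q).
#' @param sites data.frame with columns `site_id`, `a_iso` (MHz, signed),
#'   `fukui`, `sne`, and optionally `hirshfeld_charge`, `spin_density`.
#' @param mechanism One of "ET", "PCET", "unknown".
#' @return A `molecule_record` list.
#' @export
molecule_record <- function(molecule_id, family, series, ip, nucleophilicity,
                            e_homo, g_mol, log_p, sites,
                            mechanism = "unknown") {
  if (!family %in% .families) {
    stop("family must be one of: ", paste(.families, collapse = ", "))
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (nrow(sites) < 1) stop("a molecule needs at least one site")
  if (anyDuplicated(sites$site_id)) stop("site_id must be unique in molecule")
  stopifnot(all(c("site_id", "a_iso", "fukui", "sne") %in% names(sites)))
  structure(list(molecule_id = molecule_id, family = family, series = series,
                 ip = ip, nucleophilicity = nucleophilicity, e_homo = e_homo,
                 g_mol = g_mol, log_p = log_p, mechanism = mechanism,
                 sites = sites),
            class = "molecule_record")
}
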
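#' Candidate radical hypothesis for a molecule
#'
#' A molecule forming its radical by electron transfer (ET) or by
#' proton-coupled electron transfer (PCET) yields different radicals,
#' hence different g-factors and per-site hyperfine couplings. Both
#' candidates are carried until the Kaptein-rule comparison against the
#' observed polarization phases selects one.
#'
#' @param mechanism "ET" or "PCET".
#' @param g_radical Radical g-factor.
#' @param a_iso_by_site Named numeric vector, signed a_iso (MHz) per
#'   site_id.
#' @return A `radical_hypothesis` list.
#' @export
radical_hypothesis <- function(mechanism, g_radical, a_iso_by_site) {
  mechanism <- match.arg(mechanism, c("ET", "PCET"))
  stopifnot(is.numeric(a_iso_by_site), !is.null(names(a_iso_by_site)))
  structure(list(mechanism = mechanism, g_radical = g_radical,
                 a_iso_by_site = a_iso_by_site),
            class = "radical_hypothesis")
}

#' Kaptein net-effect sign rule
#'
#' Predicts whether net CIDNP polarization of a nucleus is absorptive (+1)
#' or emissive (-1) as the product of four signs:
#' Gamma_net = mu * eps * sign(Delta g) * sign(a_iso),
#' where mu is +1 for a triplet precursor and -1 for singlet, eps is +1
#' for recombination products and -1 for escape products. The result is 0
#' iff Delta g = 0 or a_iso = 0 (no net effect).
#'
#' @param mu Precursor multiplicity sign, +1 or -1.
#' @param eps Product-channel sign, +1 or -1.
#' @param delta_g_signed Signed g-factor difference (convention:
#'   g_dye - g_radical; the convention is configurable upstream).
#' @param a_iso_signed Signed hyperfine coupling, MHz.
#' @return +1, -1 or 0 (vectorized over `delta_g_signed`/`a_iso_signed`).
#' @examples
#' kaptein_net_sign(1, 1, 2e-4, -3.5)
#' @export
kaptein_net_sign <- function(mu, eps, delta_g_signed, a_iso_signed) {
  stopifnot(all(mu %in% c(-1, 1)), all(eps %in% c(-1, 1)))
  as.integer(mu * eps * sign(delta_g_signed) * sign(a_iso_signed))
}

#' Assign the radical-formation mechanism of a molecule
#'
#' For each candidate radical the per-site net polarization sign is
#' predicted by [kaptein_net_sign()] with Delta g = g_dye - g_radical, and
#' compared with the experimentally observed signs. The hypothesis whose
#' predictions agree with the largest fraction of sites is chosen; exact
#' ties are reported as "ambiguous", never silently broken.
#'
#' @param hypotheses List of [radical_hypothesis()] (at most one ET and
#'   one PCET).
#' @param observed_signs Named vector (site_id -> +1/-1) of observed
#'   polarization phases.
#' @param g_dye Dye radical g-factor.
#' @param mu,eps Kaptein convention signs; see [pipeline_config()].
#' @return A `mechanism_assignment`: list with `chosen` ("ET", "PCET" or
#'   "ambiguous"), `agreement` (named fractions per hypothesis), and
#'   `predicted_signs` (per hypothesis, per site).
#' @export
assign_mechanism <- function(hypotheses, observed_signs, g_dye,
                             mu = 1L, eps = 1L) {
  if (length(observed_signs) == 0) {
    stop("input error: no observed site signs")
  }
  if (length(hypotheses) == 0) stop("input error: no hypotheses")
  mechs <- vapply(hypotheses, function(h) h$mechanism, character(1))
  if (anyDuplicated(mechs)) {
    stop("at most one hypothesis per mechanism is allowed")
  }
  preds <- list()
  agree <- numeric(length(hypotheses))
  names(agree) <- mechs
  for (i in seq_along(hypotheses)) {
    h <- hypotheses[[i]]
    sites <- names(observed_signs)
    a <- h$a_iso_by_site[sites]
    if (anyNA(a)) {
      stop("hypothesis ", h$mechanism, " lacks a_iso for site(s): ",
           paste(sites[is.na(a)], collapse = ", "))
    }
    p <- kaptein_net_sign(mu, eps, g_dye - h$g_radical, a)
    names(p) <- sites
    preds[[h$mechanism]] <- p
    agree[i] <- mean(p == observed_signs[sites])
  }
  ord <- order(agree, decreasing = TRUE)
  chosen <- if (length(agree) > 1 && agree[ord[1]] == agree[ord[2]]) {
    "ambiguous"
  } else {
    mechs[ord[1]]
  }
  structure(list(chosen = chosen, agreement = agree,
                 predicted_signs = preds),
            class = "mechanism_assignment")
}

#' Install the chosen radical's parameters into a molecule record
#'
#' Replaces the molecule's g-factor and per-site a_iso with the values of
#' the mechanism selected by [assign_mechanism()], so that Delta g and Q
#' in the assembled feature table reflect the operative radical. The
#' operation is idempotent.
#'
#' @param molecule A [molecule_record()].
#' @param assignment A `mechanism_assignment` with `chosen != "ambiguous"`.
#' @param hypotheses The list of [radical_hypothesis()] that was assigned.
#' @return The updated `molecule_record` with `mechanism` set.
#' @export
select_radical_features <- function(molecule, assignment, hypotheses) {
  if (identical(assignment$chosen, "ambiguous")) {
    stop("unresolved-mechanism error: assignment is ambiguous for ",
         molecule$molecule_id)
  }
  mechs <- vapply(hypotheses, function(h) h$mechanism, character(1))
  h <- hypotheses[[match(assignment$chosen, mechs)]]
  a <- h$a_iso_by_site[molecule$sites$site_id]
  if (anyNA(a)) {
    stop("chosen hypothesis lacks a_iso for some sites of ",
         molecule$molecule_id)
  }
  molecule$sites$a_iso <- unname(a)
  molecule$g_mol <- h$g_radical
  molecule$mechanism <- h$mechanism
  molecule
}
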
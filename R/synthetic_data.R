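#' Parameters of the synthetic compound-library generator
#'
#' Defaults emulate the structure of the screening library the analysis is
#' designed for: three derivative families (27 indole, 5 amino-acid and 8
#' phenol derivatives), 3-7 observable proton sites per molecule,
#' per-molecule Fukui indices on the simplex (Dirichlet), hyperfine
#' couplings linearly coupled to the Fukui index, a Marcus-like quadratic
#' dependence of enhancement on the ionization potential, multiplicative
#' lognormal SNE noise with a detection floor, and a planted within-
#' molecule concordance probability between the maximal-Fukui and
#' maximal-SNE site.
#'
#' @param molecules_per_family Named integer vector (indole, amino_acid,
#'   phenol).
#' @param sites_range Integer length-2: min/max proton sites per molecule.
#' @param fukui_dirichlet_alpha Dirichlet concentration for per-site Fukui
#'   indices.
#' @param kappa a_iso-Fukui coupling slope, MHz per unit f-.
#' @param sigma_a Gaussian noise on a_iso, MHz.
#' @param ip_optimum Enhancement-optimal ionization potential, eV.
#' @param marcus_lambda Quadratic (Marcus-like) width parameter, eV^-2.
#' @param gamma Exponent of the Fukui site effect on SNE.
#' @param mol_scale_meanlog,mol_scale_sdlog Lognormal molecule-level
#'   enhancement scale.
#' @param sne_noise_sdlog Lognormal multiplicative site noise on SNE.
#' @param detection_floor Minimal reported SNE (sub-threshold sites are
#'   clipped here).
#' @param concordance Probability that a molecule's maximal-SNE site is
#'   its maximal-Fukui site (planted exactly, per molecule).
#' @param series_attenuation Named list of multiplicative SNE attenuation
#'   per substituent series (e.g. `list(N = 0.2)` for the positively
#'   charged amino series, whose electron transfer is hindered).
#' @param seed Integer seed.
#' @return A `generator_params` list.
#' @export
generator_params <- function(molecules_per_family = c(indole = 27L,
                                                      amino_acid = 5L,
                                                      phenol = 8L),
                             sites_range = c(3L, 7L),
                             fukui_dirichlet_alpha = 1.2,
                             kappa = 90,
                             sigma_a = 8,
                             ip_optimum = 7.5,
                             marcus_lambda = 0.6,
                             gamma = 1,
                             mol_scale_meanlog = log(150),
                             mol_scale_sdlog = 0.8,
                             sne_noise_sdlog = 0.25,
                             detection_floor = 0.5,
                             concordance = 0.925,
                             series_attenuation = list(N = 0.2),
                             seed = 1L) {
  stopifnot(sigma_a >= 0, sne_noise_sdlog >= 0, mol_scale_sdlog >= 0,
            concordance >= 0, concordance <= 1,
            sites_range[1] >= 1, sites_range[2] >= sites_range[1],
            all(molecules_per_family >= 1))
  structure(as.list(environment()), class = "generator_params")
}

.rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  g / sum(g)
}

.family_presets <- list(
  indole = list(series = c("H", "M", "F", "N", "O"),
                log_p_mean = 2.1, ip_mean = 7.3),
  amino_acid = list(series = c("W", "Y"),
                    log_p_mean = -1.0, ip_mean = 8.0),
  phenol = list(series = c("H", "M", "O"),
                log_p_mean = 1.5, ip_mean = 7.8)
)

#' Generate a synthetic compound library with planted ground truth
#'
#' Draws a full per-site feature table with the hierarchy the analysis
#' assumes: family/series-level logP; molecule-level IP (with the
#' nucleophilicity index anticorrelated and the LUMO-HOMO gap positively
#' correlated with IP) and |Delta g|; site-level Fukui indices summing to
#' one per molecule; a_iso = kappa * f- + noise; Q computed through
#' [geminate_polarization_q()]; and latent SNE = S_mol * f-^gamma *
#' exp(-lambda (IP - IP_opt)^2) * lognormal noise, clipped at the
#' detection floor. Whether each molecule's maximal-SNE site coincides
#' with its maximal-Fukui site is planted exactly by a per-molecule
#' Bernoulli(concordance) draw (values are swapped between sites to make
#' or break the agreement), so the concordance parameter is the exact
#' binomial hit probability.
#'
#' @param params A [generator_params()].
#' @param config A [pipeline_config()] (field, dye g-factor, Q scale).
#' @return List with `table` (a [feature_table()]) and `ground_truth`
#'   (data.frame per molecule: planted concordance flag, maximal-Fukui
#'   and maximal-SNE site, latent molecule scale).
#' @export
generate_library <- function(params = generator_params(),
                             config = pipeline_config()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(derive_seed(params$seed, "library"))
  rows <- list(); gt <- list(); mol_i <- 0L
  for (family in names(params$molecules_per_family)) {
    preset <- .family_presets[[family]]
    for (k in seq_len(params$molecules_per_family[[family]])) {
      mol_i <- mol_i + 1L
      id <- sprintf("%s%02d", toupper(substr(family, 1, 1)), k)
      series <- sample(preset$series, 1)
      log_p <- stats::rnorm(1, preset$log_p_mean, 0.5)
      ip <- stats::rnorm(1, preset$ip_mean, 0.4)
      nucleophilicity <- 3.0 - 1.2 * (ip - params$ip_optimum) +
        stats::rnorm(1, 0, 0.15)
      e_homo <- -0.9 * ip - 0.6 + stats::rnorm(1, 0, 0.1)
      delta_g <- stats::rlnorm(1, log(3e-4), 0.5)
      g_mol <- config$g_dye - sample(c(-1, 1), 1) * delta_g
      n_sites <- sample(seq(params$sites_range[1], params$sites_range[2]), 1)
      fukui <- .rdirichlet1(n_sites, params$fukui_dirichlet_alpha)
      a_iso <- params$kappa * fukui + stats::rnorm(n_sites, 0, params$sigma_a)
      q <- geminate_polarization_q(a_iso, config$g_dye, g_mol,
                                   config$b0) / config$q_scale
      atten <- params$series_attenuation[[series]] %||% 1
      s_mol <- stats::rlnorm(1, params$mol_scale_meanlog,
                             params$mol_scale_sdlog) * atten
      sne <- s_mol * fukui^params$gamma *
        exp(-params$marcus_lambda * (ip - params$ip_optimum)^2) *
        stats::rlnorm(n_sites, 0, params$sne_noise_sdlog)
      sne <- pmax(sne, params$detection_floor)
      # plant concordance exactly: swap SNE values to make or break the
      # within-molecule argmax agreement
      concordant <- stats::runif(1) < params$concordance
      i_f <- which.max(fukui); i_s <- which.max(sne)
      if (concordant && i_s != i_f) {
        sne[c(i_f, i_s)] <- sne[c(i_s, i_f)]
      } else if (!concordant && i_s == i_f && n_sites > 1) {
        j <- sample(setdiff(seq_len(n_sites), i_f), 1)
        sne[c(i_f, j)] <- sne[c(j, i_f)]
      }
      rows[[mol_i]] <- data.frame(
        molecule_id = id, family = family, series = series,
        site_id = as.character(seq_len(n_sites)),
        ip = ip, nucleophilicity = nucleophilicity,
        lumo_homo = lumo_homo_gap(e_homo, config$e_lumo_dye),
        delta_g = delta_g, a_iso = a_iso, fukui = fukui, q_value = q,
        log_p = log_p, sne = sne, stringsAsFactors = FALSE)
      gt[[mol_i]] <- data.frame(
        molecule_id = id, planted_concordant = concordant && n_sites > 1 ||
          n_sites == 1,
        fukui_argmax_site = as.character(which.max(fukui)),
        sne_argmax_site = as.character(which.max(sne)),
        s_mol = s_mol, stringsAsFactors = FALSE)
    }
  }
  list(table = feature_table(do.call(rbind, rows),
                             q_scale = config$q_scale),
       ground_truth = do.call(rbind, gt))
}

#' Generate a class-structured synthetic site table
#'
#' Produces a per-site table whose SNE marginal hits requested class
#' counts exactly (low / medium / high under the configured thresholds),
#' with feature-class separation controlled by a single parameter:
#' each feature's class mean is shifted by `separation` standard
#' deviations between adjacent classes. `separation = 0` gives features
#' carrying no class information (classifier accuracy ~ class prior);
#' large separation makes classes linearly separable.
#'
#' @param params A [generator_params()] (seed and detection floor used).
#' @param class_proportions Length-3 proportions (low, medium, high)
#'   summing to 1.
#' @param n_sites Total number of proton sites.
#' @param separation Between-class feature shift in SD units.
#' @param config A [pipeline_config()].
#' @return A [feature_table()] with attribute `class_counts`.
#' @export
generate_class_structured <- function(params = generator_params(),
                                      class_proportions = c(143, 40, 7) / 190,
                                      n_sites = 190,
                                      separation = 1.5,
                                      config = pipeline_config()) {
  if (length(class_proportions) != 3 ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must be 3 values summing to 1")
  }
  counts <- floor(class_proportions * n_sites)
  rem <- n_sites - sum(counts)
  if (rem > 0) {
    ord <- order(class_proportions * n_sites - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  if (any(counts < 2)) {
    stop("infeasible class counts for table size: ",
         paste(counts, collapse = "/"))
  }
  set.seed(derive_seed(params$seed, "class-structured"))
  thr <- config$class_thresholds
  cls <- rep(c(1L, 2L, 3L), counts)  # 1=low, 2=medium, 3=high
  sne <- numeric(n_sites)
  sne[cls == 1L] <- stats::runif(counts[1], params$detection_floor,
                                 thr[1] - 1e-6)
  sne[cls == 2L] <- stats::runif(counts[2], thr[1], thr[2])
  sne[cls == 3L] <- stats::runif(counts[3], thr[2] + 1e-6, 2 * thr[2])
  shift <- (cls - 2L) * separation
  z <- function(scale, base) base + scale * (shift + stats::rnorm(n_sites))
  a_iso <- z(5, 20)
  delta_g <- abs(z(5e-5, 3e-4))
  q <- geminate_polarization_q(a_iso, 2, 2 - delta_g,
                               config$b0) / config$q_scale
  df <- data.frame(
    molecule_id = sprintf("S%03d", (seq_len(n_sites) - 1L) %/% 5L + 1L),
    family = rep_len(names(.family_presets), n_sites),
    series = "X",
    site_id = as.character((seq_len(n_sites) - 1L) %% 5L + 1L),
    ip = z(0.4, 7.5), nucleophilicity = z(0.3, 3),
    lumo_homo = z(0.4, 4), delta_g = delta_g, a_iso = a_iso,
    fukui = z(0.08, 0.25), q_value = q, log_p = z(0.6, 1.5),
    sne = sne, stringsAsFactors = FALSE)
  # shuffle rows so molecules are not class blocks
  df <- df[sample.int(n_sites), ]
  tb <- feature_table(df, q_scale = config$q_scale)
  attr(tb, "class_counts") <- stats::setNames(counts,
                                              c("low", "medium", "high"))
  tb
}

#' Generate a Kaptein mechanism-assignment benchmark
#'
#' For each synthetic molecule, builds one ET and one PCET radical
#' hypothesis, picks one as the operative truth, generates the observed
#' per-site polarization signs from it through the Kaptein net-effect
#' rule, and flips each observed sign independently with probability
#' `sign_noise`. The two candidate radicals share the molecule's
#' hyperfine sign pattern (the protons sit on the same skeleton) but have
#' distinct g-factors on opposite sides of the dye's — the situation in
#' which the net-effect rule discriminates the mechanisms, since every
#' predicted site sign flips between the hypotheses.
#'
#' @param n_molecules Number of molecules.
#' @param n_sites Sites per molecule.
#' @param sign_noise Per-site sign flip probability.
#' @param g_dye Dye g-factor.
#' @param mu,eps Kaptein convention signs.
#' @param seed Integer seed.
#' @return List of per-molecule lists: `hypotheses`, `observed_signs`,
#'   `truth` ("ET" or "PCET").
#' @export
generate_mechanism_benchmark <- function(n_molecules = 500, n_sites = 5,
                                         sign_noise = 0.1, g_dye = 2.00300,
                                         mu = 1L, eps = 1L, seed = 1L) {
  set.seed(derive_seed(seed, "mechanism-benchmark"))
  lapply(seq_len(n_molecules), function(i) {
    sites <- as.character(seq_len(n_sites))
    a_signs <- sample(c(-1, 1), n_sites, replace = TRUE)
    side_et <- sample(c(-1, 1), 1)
    mk <- function(mech, side) {
      g <- g_dye + side * stats::rlnorm(1, log(4e-4), 0.4)
      a <- a_signs * (0.5 + stats::rlnorm(n_sites, log(10), 0.6))
      radical_hypothesis(mech, g, stats::setNames(a, sites))
    }
    hyps <- list(mk("ET", side_et), mk("PCET", -side_et))
    truth <- sample(c("ET", "PCET"), 1)
    h <- hyps[[match(truth, c("ET", "PCET"))]]
    obs <- kaptein_net_sign(mu, eps, g_dye - h$g_radical, h$a_iso_by_site)
    flip <- stats::runif(n_sites) < sign_noise
    obs[flip] <- -obs[flip]
    list(hypotheses = hyps,
         observed_signs = stats::setNames(obs, sites),
         truth = truth)
  })
}
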
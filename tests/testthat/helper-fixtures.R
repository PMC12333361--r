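# Fixtures are built in code; no data files.

# Random valid charge table: total charge difference between the N and
# N-1 electron states is exactly +1 e.
random_charge_table <- function(n_atoms = 10, n_sites = 3) {
  ids <- sprintf("A%d", seq_len(n_atoms))
  qn <- rnorm(n_atoms, 0, 0.2)
  d <- rgamma(n_atoms, 1)
  d <- d / sum(d)  # per-atom share of the removed electron
  ct <- charge_table("mol", ids, qn, qn + d,
                     site_map = data.frame(
                       site_id = as.character(seq_len(n_sites)),
                       heavy_atom_id = sample(ids, n_sites)))
  attr(ct, "true_f") <- setNames(d, ids)
  ct
}

# Minimal hand-built feature table: one value per argument vector entry.
tiny_table <- function(molecule_id, site_id, fukui, sne,
                       family = "indole", series = "H",
                       a_iso = 10, extra = NULL) {
  n <- length(site_id)
  df <- data.frame(
    molecule_id = molecule_id, family = family, series = series,
    site_id = as.character(site_id),
    ip = 7.5, nucleophilicity = 3, lumo_homo = 4, delta_g = 3e-4,
    a_iso = a_iso, fukui = fukui, q_value = 1, log_p = 2, sne = sne,
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  feature_table(df)
}

# Table whose SNE is an exact linear function of the features, for
# noiseless regression recovery. SNE kept positive.
linear_response_table <- function(n = 150, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    molecule_id = sprintf("M%03d", seq_len(n)), family = "indole",
    series = "H", site_id = "1",
    ip = rnorm(n, 7.5, 0.5), nucleophilicity = rnorm(n, 3, 0.5),
    lumo_homo = rnorm(n, 4, 0.5), delta_g = abs(rnorm(n, 3e-4, 1e-4)),
    a_iso = rnorm(n, 20, 5), fukui = runif(n, 0, 0.6),
    q_value = abs(rnorm(n, 500, 100)), log_p = rnorm(n, 2, 0.7),
    stringsAsFactors = FALSE)
  df$sne <- 100 + 40 * df$fukui + 2 * df$a_iso - 5 * df$log_p
  feature_table(df)
}
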
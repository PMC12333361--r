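test_that("condensed Fukui index localizes the removed electron", {
  ct <- charge_table("m", c("C1", "C2"), c(0, 0), c(1, 0),
                     data.frame(site_id = "1", heavy_atom_id = "C1"))
  f <- condensed_fukui(ct)
  expect_equal(unname(f["1"]), 1)
  expect_equal(unname(attr(f, "per_atom")), c(1, 0))

  ct4 <- charge_table("m", paste0("C", 1:4), rep(0, 4), rep(0.25, 4),
                      data.frame(site_id = as.character(1:4),
                                 heavy_atom_id = paste0("C", 1:4)))
  expect_equal(as.numeric(condensed_fukui(ct4)), rep(0.25, 4))
})

test_that("condensed Fukui equals the elementwise difference oracle and sums to 1", {
  set.seed(1)
  for (i in 1:20) {
    ct <- random_charge_table(n_atoms = 10)
    f <- condensed_fukui(ct)
    oracle <- ct$charges_nm1 - ct$charges_n  # independent difference
    expect_equal(unname(attr(f, "per_atom")), oracle, tolerance = 1e-12)
    expect_lt(abs(sum(attr(f, "per_atom")) - 1), 1e-6)
    expect_equal(as.numeric(f),
                 unname(oracle[match(ct$site_map$heavy_atom_id,
                                     ct$atom_ids)]))
  }
})

test_that("hydrogen charges fold into their bonded heavy atoms", {
  # C1 carries H1; removing the electron from (C1+H1) as 0.6 + 0.4
  ct <- charge_table("m", c("C1", "C2", "H1"),
                     c(0.0, 0.0, 0.1), c(0.6, 0.0, 0.5),
                     site_map = data.frame(site_id = "1",
                                           heavy_atom_id = "C1"),
                     hydrogen_map = data.frame(atom_id = "H1",
                                               heavy_atom_id = "C1"))
  f <- condensed_fukui(ct)
  expect_equal(unname(f["1"]), 1.0)  # 0.6 + (0.5 - 0.1)
  expect_error(condensed_fukui(
    charge_table("m", c("C1", "C2"), c(0, 0), c(1, 0),
                 data.frame(site_id = "1", heavy_atom_id = "C9"))),
    "mapping error")
})

test_that("charge-table invariant rejects non-unit electron removal", {
  expect_error(charge_table("m", c("C1", "C2"), c(0, 0), c(0.4, 0.3),
                            data.frame(site_id = "1",
                                       heavy_atom_id = "C1")),
               "\\+1 e")
})

test_that("Q matches an independent constants-based hand computation", {
  # frozen oracle: a_iso = 1 MHz, |Delta g| = 1e-3, B0 = 14.1 T with
  # mu_B = 9.2740100783e-24 J/T and hbar = 1.054571817e-34 J s gives
  # Q = (1/12) (2 pi 1e6)^2 * 1e-3 * 8.7941000592e10 * 14.1
  expect_equal(geminate_polarization_q(1, 2.003, 2.002, 14.1),
               4.079331566447e21, tolerance = 1e-10)
  # grid against an in-test reconstruction from the same constants
  ratio <- 9.2740100783e-24 / 1.054571817e-34
  for (a in c(0.1, 1, 7, 42)) {
    for (dg in c(1e-5, 3e-4, 2e-3)) {
      for (b0 in c(1, 9.4, 14.1)) {
        hand <- (1 / 12) * (a * 2 * pi * 1e6)^2 * dg * ratio * b0
        expect_equal(geminate_polarization_q(a, 2 + dg, 2, b0), hand,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("Q obeys its zero conditions and exact scaling laws", {
  expect_equal(geminate_polarization_q(0, 2.003, 2.002, 14.1), 0)
  expect_equal(geminate_polarization_q(5, 2.003, 2.003, 14.1), 0)
  a <- 3.7
  q1 <- geminate_polarization_q(a, 2.003, 2.002, 14.1)
  expect_identical(geminate_polarization_q(2 * a, 2.003, 2.002, 14.1),
                   4 * q1)
  expect_identical(geminate_polarization_q(-a, 2.003, 2.002, 14.1), q1)
  expect_equal(geminate_polarization_q(a, 2.003, 2.002, 28.2), 2 * q1)
  expect_equal(geminate_polarization_q(a, 2.005, 2.003, 14.1), 2 * q1)
  expect_error(geminate_polarization_q(1, 2.003, 2.002, -1),
               "domain error")
})

test_that("LUMO-HOMO gap is the dye-LUMO minus target-HOMO difference", {
  expect_equal(lumo_homo_gap(-5.5, -2.5), 3.0)
  expect_equal(lumo_homo_gap(-2.5, -2.5), 0)
  e_homo <- runif(20, -8, -5)
  expect_equal(lumo_homo_gap(e_homo, -2.8), -2.8 - e_homo)
})

test_that("logP passes supplied values through and estimates from SMILES", {
  v <- estimate_log_p(supplied = 2.1)
  expect_equal(as.numeric(v), 2.1)
  expect_equal(attr(v, "source"), "supplied")
  expect_error(estimate_log_p(), "missing-feature")
  # Wildman-Crippen atom-contribution reference for benzene: 1.6866
  bz <- estimate_log_p("c1ccccc1")
  expect_equal(attr(bz, "source"), "estimated")
  expect_lt(abs(as.numeric(bz) - 1.6866), 0.5)
})

test_that("assemble_features builds one 8-feature row per site", {
  cfg <- pipeline_config()
  m <- molecule_record("M1", "indole", "H", ip = 7.4,
                       nucleophilicity = 3.1, e_homo = -6.9,
                       g_mol = 2.0025, log_p = 2.1,
                       sites = data.frame(site_id = c("3", "4"),
                                          a_iso = c(45, -12),
                                          fukui = c(0.5, 0.2),
                                          sne = c(120, 30)),
                       mechanism = "ET")
  tb <- assemble_features(list(m), cfg)
  expect_equal(nrow(tb), 2)
  expect_true(all(feature_names() %in% names(tb)))
  df <- as.data.frame(tb)
  expect_equal(df$lumo_homo, rep(cfg$e_lumo_dye - (-6.9), 2))
  expect_equal(df$delta_g, rep(abs(cfg$g_dye - 2.0025), 2))
  expect_equal(df$q_value,
               geminate_polarization_q(c(45, -12), cfg$g_dye, 2.0025,
                                       cfg$b0) / cfg$q_scale)
  # deterministic: identical inputs give identical tables
  expect_identical(as.data.frame(assemble_features(list(m), cfg)), df)
  m$mechanism <- "ambiguous"
  expect_error(assemble_features(list(m), cfg), "ambiguity error")
})

test_that("mechanism-selected radical parameters flow into Delta g and Q", {
  cfg <- pipeline_config()
  sites <- data.frame(site_id = c("1", "2"), a_iso = c(10, 20),
                      fukui = c(0.3, 0.7), sne = c(15, 80))
  m <- molecule_record("P1", "phenol", "O", ip = 7.8,
                       nucleophilicity = 2.6, e_homo = -7.2,
                       g_mol = NA_real_, log_p = 1.4, sites = sites)
  hyps <- list(
    radical_hypothesis("ET", 2.0020, c("1" = 5, "2" = 9)),
    radical_hypothesis("PCET", 2.0046, c("1" = -33, "2" = 41)))
  asg <- list(chosen = "PCET")
  m2 <- select_radical_features(m, asg, hyps)
  tb <- assemble_features(list(m2), cfg)
  df <- as.data.frame(tb)
  expect_equal(df$a_iso, c(-33, 41))
  expect_equal(df$delta_g, rep(abs(cfg$g_dye - 2.0046), 2))
  expect_equal(df$mechanism, rep("PCET", 2))
})
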
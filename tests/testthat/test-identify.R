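test_that("profile scores follow the log-odds formula and drop gap columns", {
  prof <- build_profile(c("ACD", "ACD"), pseudocount = 1,
                        background = rep(1 / 20, 20))
  # two identical rows, uniform background:
  # consensus letter: log2((2 + 0.05) / (2 + 1) / 0.05)
  expect_equal(unname(prof$scores[1, "A"]), log2((2 + 0.05) / 3 / 0.05))
  # absent letter: log2((0 + 0.05) / 3 / 0.05)
  expect_equal(unname(prof$scores[1, "C"]), log2(0.05 / 3 / 0.05))
  expect_equal(prof$max_score, sum(apply(prof$scores, 1, max)))

  gappy <- build_profile(c("A-D", "A-D", "AC-"))  # col2 is 2/3 gaps: dropped
  expect_equal(gappy$length, 2L)
})

test_that("scanning an exact consensus yields max_score at its offset", {
  cons <- famsurvey_domains()$S8
  prof <- build_profile(rep(cons, 3), name = "S8")
  prot <- paste0("MKKL", cons, "EEDD")
  hit <- scan_domains(prot, prof)
  expect_equal(hit$start, 4L)
  expect_equal(hit$score, prof$max_score, tolerance = 1e-9)
  # too-short protein yields NULL with a notice
  expect_message(res <- scan_domains(substr(cons, 1, 10), prof), "shorter")
  expect_null(res)
})

test_that("scan_domains equals the exhaustive window oracle", {
  set.seed(42)
  for (i in 1:100) {
    L <- sample(5:12, 1)
    rows <- replicate(3, paste(sample(famsurvey:::AA_LETTERS, L, TRUE),
                               collapse = ""))
    prof <- build_profile(rows)
    prot <- paste(sample(c(famsurvey:::AA_LETTERS, "X"), 10 * L,
                         replace = TRUE), collapse = "")
    got <- scan_domains(prot, prof)
    want <- brute_scan(prot, prof)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(got$start, want$start)
  }
})

test_that("molecular weight is additive and matches the packaged table", {
  g <- compute_protein_properties("G")
  expect_equal(g$mw, 75.07, tolerance = 0.01)  # 57.0519 + 18.0153
  a <- compute_protein_properties("ACDEF")
  b <- compute_protein_properties("GHKLM")
  ab <- compute_protein_properties("ACDEFGHKLM")
  water <- 18.0153
  expect_equal(ab$mw, a$mw + b$mw - water, tolerance = 1e-6)
  expect_error(compute_protein_properties("ACX"), "X")
  expect_error(compute_protein_properties(""), "empty")
})

test_that("pI solves the Henderson-Hasselbalch zero crossing", {
  tbl <- aa_property_table()
  # no ionizable side chains: midpoint of the terminal pKa values
  gg <- compute_protein_properties("GGG")
  expect_equal(gg$pi, (tbl["NTERM", "pka"] + tbl["CTERM", "pka"]) / 2,
               tolerance = 2e-3)
  # basic composition above acidic composition
  expect_gt(compute_protein_properties("KKKKKG")$pi,
            compute_protein_properties("DDDDDG")$pi)
  # net charge at the returned pI is ~0 and decreases with pH
  counts <- table(factor(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         levels = famsurvey:::AA_LETTERS))
  pi <- compute_protein_properties("ACDEFGHIKLMNPQRSTVWY")$pi
  z <- famsurvey:::net_charge(counts, tbl, pi)
  expect_lt(abs(z), 1e-2)
  phs <- seq(0, 14, by = 0.5)
  zs <- vapply(phs, function(p) famsurvey:::net_charge(counts, tbl, p),
               numeric(1))
  expect_true(all(diff(zs) < 0))
})

test_that("family identification recovers the planted truth exactly", {
  cfg <- synthetic_config(seed = 5L, n_chromosomes = 2L,
                          n_background_genes = 40L, n_family_genes = 12L,
                          group_sizes = c(6L, 3L, 3L), n_tandem_pairs = 1L,
                          n_segmental_pairs = 1L, block_size = 5L,
                          n_specific = 3L, n_ubiquitous = 2L,
                          tissues = c("root", "leaf", "ovule"))
  ds <- generate_survey_dataset(cfg)
  prof <- list(
    Peptidase_S8 = build_profile(
      seed_alignment_variants(famsurvey_domains()$S8, seed = 1),
      name = "Peptidase_S8"),
    PA = build_profile(seed_alignment_variants(famsurvey_domains()$PA,
                                               seed = 1), name = "PA"),
    I9 = build_profile(seed_alignment_variants(famsurvey_domains()$I9,
                                               seed = 1), name = "I9"))
  mem <- identify_family(ds$bundle, prof, threshold_frac = 0.5)
  expect_setequal(mem$gene_id, ds$truth$family_ids)
  # members sorted by (chrom, start)
  expect_equal(order(mem$chrom, mem$start), seq_len(nrow(mem)))
  # architecture flags follow the planted group layout
  expect_equal(setNames(mem[names(ds$truth$has_pa), "has_PA"],
                        names(ds$truth$has_pa)), ds$truth$has_pa)
  expect_equal(setNames(mem[names(ds$truth$has_i9), "has_I9"],
                        names(ds$truth$has_i9)), ds$truth$has_i9)
  # an unattainable threshold empties the family
  none <- identify_family(ds$bundle, prof["Peptidase_S8"],
                          threshold_frac = 1.01)
  expect_equal(nrow(none), 0L)
})
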
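test_that("similarity search ranks self-identical subjects first and keeps 5", {
  set.seed(17)
  base <- paste(sample(famsurvey:::AA_LETTERS, 80, TRUE), collapse = "")
  queries <- c(q = base)
  subjects <- setNames(c(base, vapply(1:7, function(i)
    mutate_sequence(base, 0.1, seed = i), character(1))),
    c("exact", paste0("v", 1:7)))
  hits <- similarity_search(queries, subjects, min_score = 50)
  expect_equal(hits$subject_id[hits$rank_in_query == 1], "exact")
  expect_equal(nrow(hits), 5L)          # 8 pass the threshold, 5 retained
  expect_true(all(hits$rank_in_query == seq_len(5)))
  # self-comparison excludes self-pairs
  self_hits <- similarity_search(subjects, subjects, min_score = 50)
  expect_false(any(self_hits$query_id == self_hits$subject_id))
})

test_that("local scores equal the substring + global-alignment oracle", {
  sub <- famsurvey:::blosum62()
  set.seed(23)
  for (i in 1:8) {
    a <- paste(sample(famsurvey:::AA_LETTERS, sample(4:8, 1), TRUE),
               collapse = "")
    b <- paste(sample(famsurvey:::AA_LETTERS, sample(4:8, 1), TRUE),
               collapse = "")
    got <- similarity_search(setNames(a, "a"), setNames(b, "b"),
                             min_score = -Inf, top_n = 1)
    expect_equal(got$score, brute_local_score(a, b, sub), tolerance = 1e-9,
                 info = paste(a, b))
  }
})

test_that("chaining finds same-orientation and inverted blocks", {
  anc <- data.frame(chrom_a = "c1", rank_a = 1:5, chrom_b = "c2",
                    rank_b = 1:5, gene_a = paste0("a", 1:5),
                    gene_b = paste0("b", 1:5))
  blocks <- chain_blocks(anc, min_anchors = 5, max_gap = 25)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$orientation, "same")
  expect_equal(nrow(blocks[[1]]$anchors), 5L)

  inv <- anc
  inv$rank_b <- 5:1
  blocks <- chain_blocks(inv, min_anchors = 5, max_gap = 25)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$orientation, "inverted")

  # a gap larger than max_gap splits the chain below min_anchors
  gappy <- anc
  gappy$rank_b <- c(1, 2, 3, 30, 31)
  expect_length(chain_blocks(gappy, min_anchors = 5, max_gap = 10), 0L)
})

test_that("duplication classes follow the tandem/segmental/dispersed rules", {
  members <- data.frame(gene_id = c("m1", "m2", "m3", "m4", "m5", "m6"),
                        chrom = c("c1", "c1", "c1", "c2", "c1", "c3"),
                        rank = c(5L, 6L, 40L, 7L, 80L, 2L),
                        stringsAsFactors = FALSE)
  hits <- data.frame(
    query_id =  c("m1", "m2", "m3", "m5", "m4", "m6"),
    subject_id = c("m2", "m1", "m5", "m3", "m6", "m4"),
    score = 100, rank_in_query = 1L, stringsAsFactors = FALSE)
  blocks <- list(list(chrom_a = "c2", chrom_b = "c3", orientation = "same",
                      anchors = data.frame(gene_a = c("x1", "m4"),
                                           gene_b = c("y1", "m6"))))
  dup <- classify_duplications(members, hits, blocks, tandem_max_gap = 1)
  expect_equal(dup$dup_type[dup$gene_a == "m1"], "tandem")
  expect_equal(dup$dup_type[dup$gene_a == "m3"], "dispersed")  # gap 40
  expect_equal(dup$dup_type[dup$gene_a == "m4"], "segmental")
})

test_that("codon alignment maps columns and drops gaps, Ns and stops", {
  cds_a <- "ATGAAACCC"
  cds_b <- "ATGCCC"
  al <- global_align(famsurvey:::translate_cds(cds_a),
                     famsurvey:::translate_cds(cds_b))
  cp <- codon_align(cds_a, cds_b, al$a, al$b)
  expect_equal(nrow(cp), 2L)
  expect_equal(attr(cp, "gap_columns"), 1L)

  # identical sequences: every codon paired
  cp2 <- codon_align(cds_a, cds_a, "MKP", "MKP")
  expect_equal(nrow(cp2), 3L)
  expect_equal(attr(cp2, "dropped"), 0L)

  # N-containing codons dropped with a count
  cp3 <- codon_align("ATGANTCCC", "ATGAAACCC", "MXP", "MKP")
  expect_equal(nrow(cp3), 2L)
  expect_equal(attr(cp3, "dropped"), 1L)

  # terminal stop stripped, translation mismatch caught
  expect_equal(nrow(codon_align("ATGAAATAA", "ATGAAA", "MK", "MK")), 2L)
  expect_error(codon_align("ATGAAA", "ATGCCC", "MK", "MK"),
               "translation mismatch")
})

test_that("NG86 site counts match the neighbor-enumeration examples", {
  tb <- famsurvey:::ng86_tables()
  # TTT: only TTT->TTC synonymous among its 9 non-stop neighbors
  expect_equal(tb$S_c[["TTT"]], 1 / 3)
  # GTT: third position fully degenerate
  expect_equal(tb$S_c[["GTT"]], 1)
  # stop-adjusted denominators: TGG's third position has only two non-stop
  # neighbors (TGA excluded), both nonsynonymous; ATG is fully unique
  expect_equal(tb$S_c[["TGG"]], 0)
  expect_equal(tb$S_c[["ATG"]], 0)
  code <- Biostrings::GENETIC_CODE
  nonstop <- names(code)[code != "*"]
  expect_true(all(tb$S_c[nonstop] >= 0 & tb$S_c[nonstop] <= 3))

  # pair TTT/GTT: one nonsynonymous difference
  r <- ng86_kaks(cbind("TTT", "GTT"))
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 1)
  expect_equal(r$S_sites, (1 / 3 + 1) / 2)
})

test_that("identical sequences give Ka = Ks = 0 and an undefined ratio", {
  cp <- cbind(c("ATG", "AAA", "CCC"), c("ATG", "AAA", "CCC"))
  r <- ng86_kaks(cp)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
  expect_equal(r$selection, "undefined")
})

test_that("NG86 equals the independent pathway-enumeration oracle", {
  set.seed(31)
  for (i in 1:60) {
    cp <- random_codon_pairs(sample(1:30, 1))
    got <- ng86_kaks(cp)
    want <- ng86_oracle(cp)
    expect_equal(got$S_sites, want$S, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$Ka, want$Ka, tolerance = 1e-9)
    expect_equal(got$Ks, want$Ks, tolerance = 1e-9)
  }
})

test_that("median Ka is monotone in planted nonsynonymous divergence", {
  cfg_at <- function(nonsyn) {
    synthetic_config(seed = 2L, n_chromosomes = 2L, n_background_genes = 40L,
                     n_family_genes = 12L, group_sizes = c(6L, 3L, 3L),
                     n_tandem_pairs = 1L, n_segmental_pairs = 1L,
                     block_size = 5L, n_specific = 3L, n_ubiquitous = 2L,
                     tissues = c("root", "leaf", "ovule"),
                     nonsyn_divergence = nonsyn)
  }
  med_ka <- vapply(c(0.02, 0.10, 0.25), function(nv) {
    ds <- generate_survey_dataset(cfg_at(nv))
    median(vapply(seq_len(nrow(ds$truth$pairs)), function(i)
      pair_kaks(ds$bundle, ds$truth$pairs$gene_a[i],
                ds$truth$pairs$gene_b[i])$Ka, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_ka) >= 0))
})
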
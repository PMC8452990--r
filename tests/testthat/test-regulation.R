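test_that("element table validates IUPAC codes and categories", {
  tbl <- read_element_table()
  expect_true(all(c("Box 4", "G-box", "ABRE", "ARE", "CGTCA-motif") %in%
                    tbl$name))
  expect_setequal(unique(tbl$category),
                  c("growth_development", "stress", "phytohormone"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tconsensus\tcategory", "bad\tACGQ\tstress"), f)
  expect_error(read_element_table(f), "invalid IUPAC")
})

test_that("promoter extraction follows the upstream arithmetic", {
  b <- toy_bundle()  # genes at [1000,1300) and [6000,6300), both +
  pr <- extract_promoters(b, length = 2000)
  p1 <- pr[pr$gene_id == "g1", ]
  # chromosome-start clip: [0, 1000), truncated
  expect_equal(c(p1$start, p1$end), c(0, 1000))
  expect_true(p1$truncated)
  p2 <- pr[pr$gene_id == "g2", ]
  # full 2000 bp window [4000, 6000); no overlap with g1 (ends 1300)
  expect_equal(c(p2$start, p2$end), c(4000, 6000))
  expect_false(p2$truncated)
  expect_equal(nchar(p2$seq), 2000L)
  # the promoter never overlaps its own gene body
  expect_true(p2$end <= 6000)
})

test_that("upstream-gene overlap is deleted from the promoter", {
  b <- toy_bundle()
  # add an upstream gene spanning [4500, 4800) before g2 at [6000, 6300)
  g <- data.frame(gene_id = c(b$genes$gene_id, "gU"),
                  chrom = "c1",
                  start = c(b$genes$start, 4500L),
                  end = c(b$genes$end, 4800L),
                  strand = "+", stringsAsFactors = FALSE)
  g$exons <- c(b$genes$exons, list(cbind(4500L, 4800L)))
  g <- famsurvey:::compute_ranks(g)
  rownames(g) <- g$gene_id
  b2 <- b
  b2$genes <- g
  pr <- extract_promoters(b2, "g2", length = 2000)
  expect_equal(c(pr$start, pr$end), c(4800, 6000))
  expect_true(pr$truncated)
})

test_that("minus-strand promoters are downstream and reverse-complemented", {
  b <- toy_bundle()
  b$genes["g2", "strand"] <- "-"
  pr <- extract_promoters(b, "g2", length = 500)
  expect_equal(c(pr$start, pr$end), c(6300, 6800))
  expect_identical(pr$seq,
                   famsurvey:::revcomp(substring(b$chromosomes[["c1"]],
                                                 6301, 6800)))
})

test_that("IUPAC scanning reports all offsets on both strands", {
  tbl <- data.frame(name = c("ABRE", "pal"),
                    consensus = c("ACGTG", "CACGTG"),
                    category = c("phytohormone", "growth_development"),
                    stringsAsFactors = FALSE)
  pr <- data.frame(gene_id = "g", seq = "TTACGTGT", stringsAsFactors = FALSE)
  hits <- scan_elements(pr, tbl)
  fw <- hits[hits$element == "ABRE" & hits$strand == "+", ]
  expect_equal(fw$offset, 2L)
  # palindromic consensus: forward and reverse hits at the same offset
  pr2 <- data.frame(gene_id = "g", seq = "AACACGTGAA", stringsAsFactors = FALSE)
  hits2 <- scan_elements(pr2, tbl)
  pal <- hits2[hits2$element == "pal", ]
  expect_setequal(pal$strand, c("-", "+"))
  expect_equal(unique(pal$offset), 2L)
})

test_that("scanning equals the naive IUPAC-expansion oracle", {
  tbl <- read_element_table()
  set.seed(5)
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    got <- scan_elements(data.frame(gene_id = "p", seq = seq), tbl)
    want <- naive_scan(seq, tbl)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$offset, want$offset)
    expect_equal(got$element, want$element)
    expect_equal(got$strand, want$strand)
  }
})

test_that("reverse-complementing the promoter mirrors the hit set", {
  tbl <- read_element_table()
  set.seed(6)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  fw <- scan_elements(data.frame(gene_id = "p", seq = seq), tbl)
  rv <- scan_elements(data.frame(gene_id = "p",
                                 seq = famsurvey:::revcomp(seq)), tbl)
  widths <- setNames(nchar(tbl$consensus), tbl$name)
  mirrored <- data.frame(element = fw$element,
                         offset = 500L - fw$offset - widths[fw$element],
                         strand = ifelse(fw$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$element, d$offset, d$strand))
  expect_identical(key(rv), key(mirrored))
})

test_that("category census percentages and totals are consistent", {
  tbl <- data.frame(name = c("e1", "e2", "e3"),
                    consensus = c("AAAA", "CCCC", "GGGG"),
                    category = c("growth_development", "stress",
                                 "phytohormone"), stringsAsFactors = FALSE)
  hits <- data.frame(gene_id = c("g1", "g1", "g1", "g2", "g2"),
                     element = c("e1", "e1", "e1", "e2", "e3"),
                     offset = 1:5, strand = "+", stringsAsFactors = FALSE)
  cz <- summarize_categories(hits, tbl)
  expect_equal(cz$total, 5L)
  expect_equal(cz$n_types, 3L)
  expect_equal(sum(cz$by_category$pct), 100, tolerance = 0.01)
  expect_equal(cz$by_category$pct[cz$by_category$category ==
                                    "growth_development"], 60)
  # within-category percentages also sum to 100 per category
  agg <- tapply(cz$by_element$pct_within_category, cz$by_element$category, sum)
  expect_true(all(abs(agg - 100) < 0.01))
  # census total equals the hit-list length (one category per element)
  expect_equal(sum(cz$by_category$n), nrow(hits))
  expect_equal(unname(cz$per_gene["g1", "e1"]), 3L)

  empty <- summarize_categories(hits[0, ], tbl)
  expect_true(empty$empty)
  expect_equal(empty$total, 0L)
})
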
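test_that("global alignment handles identities and trivial pairs", {
  sub <- famsurvey:::blosum62()
  s <- "HEAGAWGHEE"
  al <- global_align(s, s)
  expect_identical(al$a, s)
  expect_identical(al$b, s)
  expect_equal(al$score, sum(diag(sub[strsplit(s, "")[[1]],
                                      strsplit(s, "")[[1]]])))
  one <- global_align("A", "G")
  expect_equal(one$score, sub["A", "G"])
  expect_error(global_align("", "A"), "empty")
})

test_that("global alignment equals exhaustive path enumeration on short pairs", {
  sub <- famsurvey:::blosum62()
  set.seed(9)
  for (i in 1:25) {
    a <- paste(sample(famsurvey:::AA_LETTERS, sample(2:8, 1), TRUE),
               collapse = "")
    b <- paste(sample(famsurvey:::AA_LETTERS, sample(2:8, 1), TRUE),
               collapse = "")
    expect_equal(global_align(a, b)$score,
                 brute_global_score(a, b, sub), tolerance = 1e-9,
                 info = paste(a, b))
  }
})

test_that("progressive MSA reduces to pairwise alignment and keeps identities", {
  s <- c(x = "MKVLHEAGAWGHEE", y = "MKVLHEAGAWGHEE", z = "MKVLHEAGAWGHEE")
  aln <- progressive_msa(s)
  expect_identical(unname(aln), unname(s))  # identical sequences: no gaps
  two <- c(p = "HEAGAWGHEE", q = "PAWHEAE")
  ga <- global_align(two[[1]], two[[2]])
  expect_identical(unname(progressive_msa(two)), c(ga$a, ga$b))
})

test_that("progressive MSA aligns planted domain columns", {
  cons <- famsurvey_domains()$S8
  set.seed(21)
  seqs <- setNames(lapply(1:8, function(i) {
    left <- paste(sample(famsurvey:::AA_LETTERS, sample(10:40, 1), TRUE),
                  collapse = "")
    right <- paste(sample(famsurvey:::AA_LETTERS, sample(10:40, 1), TRUE),
                   collapse = "")
    dom <- mutate_sequence(cons, 0.05, seed = 100 + i)
    paste0(left, dom, right)
  }), paste0("s", 1:8))
  aln <- progressive_msa(unlist(seqs))
  rows <- do.call(rbind, strsplit(unname(aln), ""))
  # map each row's ungapped positions back to sequence coordinates
  dom_cols <- function(row_idx) {
    s <- unlist(seqs)[[row_idx]]
    dom <- mutate_sequence(cons, 0.05, seed = 100 + row_idx)
    at <- regexpr(dom, s, fixed = TRUE)[1]
    pos <- which(rows[row_idx, ] != "-")
    pos[at:(at + nchar(cons) - 1)]
  }
  anchor <- dom_cols(1)
  agree <- vapply(2:8, function(r) mean(dom_cols(r) == anchor), numeric(1))
  expect_gte(mean(agree), 0.95)  # >= 95% of domain columns co-aligned
})

test_that("distance models match their closed forms", {
  aln <- c(a = "AAAA", b = "AAAT")
  expect_equal(distance_matrix(aln, "p")["a", "b"], 0.25)
  aln2 <- c(a = paste(rep("A", 10), collapse = ""),
            b = paste(c(rep("A", 9), "C"), collapse = ""))
  expect_equal(distance_matrix(aln2, "poisson")["a", "b"], -log(0.9),
               tolerance = 1e-9)
  same <- c(x = "MKV", y = "MKV")
  expect_equal(distance_matrix(same, "p")["x", "y"], 0)
  expect_equal(distance_matrix(same, "poisson")["x", "y"], 0)
  nogap <- c(x = "A--", y = "-AA")
  expect_error(distance_matrix(nogap), "no shared")
})

test_that("NJ recovers the worked four-taxon additive example", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  expect_identical(unrooted_splits(tr), "C|D")  # the AB|CD bipartition
  # internal branch length 1, leaf branches 1,2,3,4
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 2, 3,
                2, 0, 5,
                3, 5, 0), 3, 3, dimnames = list(c("x", "y", "z"),
                                                c("x", "y", "z")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["x"]], (2 + 3 - 5) / 2)
  expect_equal(bl[["y"]], (2 + 5 - 3) / 2)
  expect_equal(bl[["z"]], (3 + 5 - 2) / 2)
})

test_that("NJ exactly recovers random additive trees", {
  set.seed(4)
  for (i in 1:20) {
    case <- random_additive_case(sample(5:12, 1))
    tr <- nj_tree(case$D)
    expect_identical(unrooted_splits(tr), unrooted_splits(case$tree))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(case$D), colnames(case$D)],
                 case$D, tolerance = 1e-8)
  }
})

test_that("NJ agrees with the independent ape implementation on topology", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    D <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    v <- runif(n * (n - 1) / 2, 0.1, 2)
    D[upper.tri(D)] <- v
    D <- D + t(D)
    tr <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_identical(unrooted_splits(tr), unrooted_splits(ref))
  }
})

test_that("bootstrap supports: separating edge of two planted clades is 1.0", {
  set.seed(13)
  base1 <- paste(sample(famsurvey:::AA_LETTERS, 120, TRUE), collapse = "")
  base2 <- paste(sample(famsurvey:::AA_LETTERS, 120, TRUE), collapse = "")
  seqs <- c(
    setNames(vapply(1:3, function(i) mutate_sequence(base1, 0.03, seed = i),
                    character(1)), paste0("a", 1:3)),
    setNames(vapply(1:3, function(i) mutate_sequence(base2, 0.03, seed = 10 + i),
                    character(1)), paste0("b", 1:3)))
  aln <- progressive_msa(seqs)
  D <- distance_matrix(aln)
  tr <- nj_tree(D, bootstrap = list(alignment = aln, n_reps = 100, seed = 1))
  sup <- attr(tr, "support")
  sep <- sup[[paste(c("b1", "b2", "b3"), collapse = "\r")]]
  expect_equal(sep, 1)
  expect_true(all(sup >= 0 & sup <= 1))
})

test_that("zero-variance alignments give support 1.0 on every edge", {
  # every column identical: resampling cannot change any replicate, so
  # all replicate trees equal the main tree and every support is 1
  aln <- setNames(vapply(c("A", "C", "D", "E", "F"), function(x)
    paste(rep(x, 40), collapse = ""), character(1)), paste0("s", 1:5))
  D <- suppressWarnings(distance_matrix(aln, "p"))
  tr <- suppressWarnings(
    nj_tree(D, bootstrap = list(alignment = aln, n_reps = 20, seed = 2,
                                model = "p")))
  sup <- attr(tr, "support")
  expect_true(length(sup) >= 1)
  expect_equal(unname(sup), rep(1, length(sup)))
})

test_that("subfamily assignment follows nearest reference and ignores order", {
  # handcrafted tree: member m1 sister to ref r1 (group G1)
  tr <- ape::read.tree(text = "((m1:0.1,r1:0.1):0.5,(r2:0.1,m2:0.1):0.5,r3:0.9);")
  labels <- c(r1 = "G1", r2 = "G2", r3 = "G3")
  asg <- assign_subfamilies(tr, labels)
  expect_equal(asg$group[asg$member == "m1"], "G1")
  expect_equal(asg$group[asg$member == "m2"], "G2")
  # invariance to leaf order: relabel-permuted tree gives same mapping
  tr2 <- ape::read.tree(text = "(r3:0.9,(r2:0.1,m2:0.1):0.5,(r1:0.1,m1:0.1):0.5);")
  asg2 <- assign_subfamilies(tr2, labels)
  expect_equal(asg[order(asg$member), c("member", "group")],
               asg2[order(asg2$member), c("member", "group")],
               ignore_attr = TRUE)
  expect_error(assign_subfamilies(tr, character(0)), "no references")
})

test_that("composition report reproduces the printed subfamily arithmetic", {
  groups <- setNames(rep("Group_I", 126), paste0("g", 1:126))
  clades <- setNames(c(rep("monocot", 87), rep("dicot", 39)),
                     paste0("g", 1:126))
  comp <- subfamily_composition(groups, clades)
  expect_equal(comp$pct[comp$clade == "monocot"], 69L)
  expect_equal(comp$pct[comp$clade == "dicot"], 31L)
})
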
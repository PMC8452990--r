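# Shared internal helpers: alphabets, seeding discipline, translation.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
DNA_LETTERS <- c("A", "C", "G", "T")
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps the generator's sub-streams isolated
# from user code and from each other.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed per named component, independent of call order.
# Stays below 2^31 - 1.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) %% 1000003) * 1009 + (h %% 99991)) %% 2147483646L + 1L
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

validate_seq <- function(seq, moltype, id = "<seq>") {
  alphabet <- if (moltype == "dna") c(DNA_LETTERS, "N") else c(AA_LETTERS, "X")
  cc <- chars(seq)
  bad <- which(!cc %in% alphabet)
  if (length(bad))
    stop(sprintf("sequence '%s': illegal %s character '%s' at position %d",
                 id, moltype, cc[bad[1L]], bad[1L]), call. = FALSE)
  invisible(TRUE)
}

# Translate a CDS string (no terminal stop expected) under the standard code.
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length not divisible by 3", call. = FALSE)
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# BLOSUM62 restricted to the 20 standard residues plus X, cached per session.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[c(AA_LETTERS, "X"), c(AA_LETTERS, "X")]
      cache <<- m
    }
    cache
  }
})

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
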
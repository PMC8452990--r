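# File-format boundary: FASTA, GFF3, expression TSV.
#
# All coordinates are 0-based half-open internally; GFF3's 1-based inclusive
# convention is converted exactly once, here. Gene "position" along a
# chromosome is its rank (0-based order by ascending start, ties broken by
# gene_id), the unit in which tandem adjacency and collinearity are defined.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and validated against the declared alphabet
#' (`A/C/G/T/N` for DNA, the 20 amino-acid letters plus `X` for protein).
#' The header token before the first whitespace becomes the record id.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"dna"` or `"protein"`.
#' @return Named character vector of sequences with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", dup[1L], call. = FALSE)
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (any(!nzchar(seqs)))
    stop("empty sequence for id: ", ids[!nzchar(seqs)][1L], call. = FALSE)
  for (i in seq_along(seqs)) validate_seq(seqs[[i]], moltype, ids[i])
  structure(seqs, moltype = moltype)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(unclass(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Consumes `gene`, `mRNA`, `exon` and `CDS` features (others are ignored
#' with a message). Coordinates are converted from GFF3's 1-based inclusive
#' convention to 0-based half-open. When a gene has several mRNA isoforms,
#' the one with the longest summed exon length represents the gene. Gene
#' ranks (0-based order by start, ties by gene_id) are computed per
#' chromosome.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `rank` and a list-column `exons` (each a 2-column matrix of
#'   0-based half-open intervals), row names = gene ids.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  keep <- c("gene", "mRNA", "exon", "CDS")
  skipped <- sum(!df$type %in% keep)
  if (skipped > 0L)
    message("read_gff3: ignored ", skipped, " feature(s) of unsupported type")
  df <- df[df$type %in% keep, , drop = FALSE]
  parent <- if ("Parent" %in% names(df))
    vapply(df$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1L)) else rep(NA_character_, nrow(df))

  genes <- df[df$type == "gene", , drop = FALSE]
  if (any(is.na(genes$ID)) || any(!nzchar(genes$ID)))
    stop("gene feature without an ID attribute", call. = FALSE)
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  mrna_parent <- parent[df$type == "mRNA"]
  exon_parent <- parent[df$type == "exon"]
  mrna_of <- setNames(mrna_parent, mrnas$ID)  # mRNA id -> gene id

  out <- data.frame(gene_id = genes$ID,
                    chrom = as.character(genes$seqnames),
                    start = genes$start - 1L,  # to 0-based half-open
                    end = genes$end,
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  exon_list <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    gid <- out$gene_id[i]
    # exons attached directly to the gene, or via its mRNAs
    direct <- exon_parent == gid
    via <- exon_parent %in% names(mrna_of)[!is.na(mrna_of) & mrna_of == gid]
    if (any(via)) {
      # longest-CDS isoform: pick the mRNA with the largest summed exon span
      mids <- unique(exon_parent[via])
      span <- vapply(mids, function(m) {
        e <- exons[exon_parent == m, , drop = FALSE]
        sum(e$end - e$start + 1L)
      }, numeric(1L))
      best <- mids[order(-span, mids)][1L]
      e <- exons[exon_parent == best, , drop = FALSE]
    } else if (any(direct)) {
      e <- exons[direct, , drop = FALSE]
    } else {
      e <- exons[0L, , drop = FALSE]
    }
    if (nrow(e)) {
      m <- cbind(start = e$start - 1L, end = e$end)
      m <- m[order(m[, 1L]), , drop = FALSE]
      if (any(m[, 1L] < out$start[i]) || any(m[, 2L] > out$end[i]))
        stop("exon outside gene span for gene ", gid, call. = FALSE)
      if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
        stop("overlapping exons for gene ", gid, call. = FALSE)
      exon_list[[i]] <- m
    } else {
      exon_list[[i]] <- cbind(start = out$start[i], end = out$end[i])
    }
  }
  names(exon_list) <- out$gene_id
  out$exons <- exon_list
  out <- compute_ranks(out)
  rownames(out) <- out$gene_id
  out
}

# rank = 0-based order by ascending start within chromosome, ties by gene_id
compute_ranks <- function(genes) {
  genes$rank <- NA_integer_
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    ord <- idx[order(genes$start[idx], genes$gene_id[idx])]
    genes$rank[ord] <- seq_along(ord) - 1L
  }
  genes
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive. Each gene is written with one mRNA
#' and its exons.
#'
#' @param genes Gene-model `data.frame` as returned by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id
    lines <- c(lines,
      sprintf("%s\tfamsurvey\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start + 1L, g$end, g$strand, gid),
      sprintf("%s\tfamsurvey\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, g$start + 1L, g$end, g$strand, gid, gid))
    ex <- genes$exons[[i]]
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines,
        sprintf("%s\tfamsurvey\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
                g$chrom, ex[k, 1L] + 1L, ex[k, 2L], g$strand, gid, k, gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-tissues FPKM matrix from TSV
#'
#' First row holds tissue labels, first column gene ids; all cells must
#' parse as finite non-negative numbers.
#'
#' @param path Path to a tab-separated table.
#' @return Numeric matrix, rows = genes, columns = tissues.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("expression table needs >= 1 tissue column", call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate gene id in expression table", call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric expression cell at row %d (gene %s), column %d (%s)",
                 bad[1L, 1L], ids[bad[1L, 1L]], bad[1L, 2L],
                 colnames(vals)[bad[1L, 2L]]), call. = FALSE)
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative expression value at row %d (gene %s), column %d (%s)",
                 neg[1L, 1L], ids[neg[1L, 1L]], neg[1L, 2L],
                 colnames(vals)[neg[1L, 2L]]), call. = FALSE)
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with gene row names and tissue column names.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a genome bundle
#'
#' The common substrate of all survey stages: chromosome sequences, gene
#' models, proteome and CDS. Validates that every gene's chromosome exists,
#' that CDS lengths are divisible by 3 and that each CDS translates to its
#' protein (up to a terminal stop).
#'
#' @param chromosomes Named character vector of chromosome sequences.
#' @param genes Gene-model `data.frame` (see [read_gff3()]).
#' @param proteome,cds Named character vectors keyed by gene id.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(chromosomes, genes, proteome, cds) {
  missing_chrom <- setdiff(unique(genes$chrom), names(chromosomes))
  if (length(missing_chrom))
    stop("gene chromosome not in genome: ", missing_chrom[1L], call. = FALSE)
  for (g in names(cds)) {
    s <- cds[[g]]
    if (nchar(s) %% 3L != 0L)
      stop("CDS length of ", g, " not divisible by 3", call. = FALSE)
    if (g %in% names(proteome)) {
      tr <- sub("\\*$", "", translate_cds(s))
      if (tr != proteome[[g]])
        stop("CDS of ", g, " does not translate to its protein", call. = FALSE)
    }
  }
  structure(list(chromosomes = chromosomes, genes = genes,
                 proteome = proteome, cds = cds),
            class = "genome_bundle")
}

#' Read a genome bundle from standard files
#'
#' @param genome_fna,gff3,proteome_faa,cds_fna File paths.
#' @return A `genome_bundle`.
#' @export
read_genome_bundle <- function(genome_fna, gff3, proteome_faa, cds_fna) {
  genome_bundle(chromosomes = read_fasta(genome_fna, "dna"),
                genes = read_gff3(gff3),
                proteome = read_fasta(proteome_faa, "protein"),
                cds = read_fasta(cds_fna, "dna"))
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", length(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "gene(s),", length(x$proteome), "protein(s)\n")
  invisible(x)
}
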
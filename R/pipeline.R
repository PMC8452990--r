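# End-to-end survey orchestration: one config in, a report directory out.

#' Survey configuration
#'
#' Collects the input paths and stage parameters of a full survey run.
#' All referenced files must exist at validation time.
#'
#' @param genome_fna,gff3,proteome_faa,cds_fna Genome bundle paths.
#' @param expression_tsv Expression matrix path (optional: `NULL` skips
#'   the expression stage).
#' @param elements_tsv Cis-element table path (default: packaged table).
#' @param refs_faa,ref_labels_tsv Reference proteins and their labels
#'   (`ref_id`, `group`, optional `clade`); optional: `NULL` skips
#'   subfamily assignment.
#' @param out_dir Output directory.
#' @param seed Integer seed (bootstrap resampling).
#' @param domain_consensus Named character vector of domain consensus
#'   strings; the first defines family membership, the rest annotate
#'   architecture. Profiles are built from seeded consensus variants.
#' @param threshold_frac Membership threshold as a fraction of the
#'   profile maximum score.
#' @param distance_model `"poisson"` or `"p"`.
#' @param bootstrap_reps Bootstrap replicates (0 disables).
#' @param min_score,top_n Similarity-search parameters.
#' @param min_anchors,max_gap Collinearity chaining parameters.
#' @param tandem_max_gap Tandem rank-gap cutoff.
#' @param promoter_length Promoter window (bp).
#' @param expressed_fpkm,tau_specific Expression-call thresholds.
#' @param member_clade Clade-of-origin tag applied to (non-reference)
#'   members in the composition report.
#' @return Object of class `survey_run_config`.
#' @export
survey_config <- function(genome_fna, gff3, proteome_faa, cds_fna,
                          expression_tsv = NULL,
                          elements_tsv = NULL,
                          refs_faa = NULL, ref_labels_tsv = NULL,
                          out_dir = "survey_out",
                          seed = 1L,
                          domain_consensus = c(
                            Peptidase_S8 = famsurvey_domains()$S8,
                            PA = famsurvey_domains()$PA,
                            Inhibitor_I9 = famsurvey_domains()$I9),
                          threshold_frac = 0.5,
                          distance_model = "poisson",
                          bootstrap_reps = 100L,
                          min_score = 50,
                          top_n = 5L,
                          min_anchors = 5L,
                          max_gap = 25L,
                          tandem_max_gap = 1L,
                          promoter_length = 2000L,
                          expressed_fpkm = 1,
                          tau_specific = 0.85,
                          member_clade = "monocot") {
  cfg <- as.list(environment())
  required <- c(genome_fna, gff3, proteome_faa, cds_fna)
  optional <- c(expression_tsv, elements_tsv, refs_faa, ref_labels_tsv)
  for (f in c(required, optional)) {
    if (!is.null(f) && !file.exists(f))
      stop("input file does not exist: ", f, call. = FALSE)
  }
  stopifnot(threshold_frac > 0, bootstrap_reps >= 0,
            distance_model %in% c("poisson", "p"))
  structure(cfg, class = "survey_run_config")
}

#' Run the full gene-family survey
#'
#' Stages: identify members -> phylogeny (alignment, NJ + bootstrap,
#' subfamily assignment, composition) -> gene structure -> duplication
#' and Ka/Ks -> promoter element census -> expression calls -> report.
#' Writes `members.tsv`, `tree.nwk`, `assignments.tsv`,
#' `gene_structure.tsv`, `duplications.tsv`, `kaks.tsv`,
#' `element_hits.tsv`, `element_census.tsv`, `per_gene_elements.tsv`,
#' `expr_calls.tsv`, `log2_matrix.tsv` and `report.json` under
#' `config$out_dir`. Identical config + seed give an identical
#' `report.json`. Any stage failure aborts with the stage name; partial
#' outputs are kept under a `failed/` marker file.
#'
#' @param config A `survey_run_config`.
#' @return The report, invisibly (a named list mirroring `report.json`).
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "survey_run_config"))
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "load_inputs"
  report <- list(parameters = cfg[!vapply(cfg, is.null, logical(1L))])
  on_fail <- function(e) {
    writeLines(paste("failed at stage:", stage, "-", conditionMessage(e)),
               file.path(out, "failed"))
    stop("survey failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    bundle <- read_genome_bundle(cfg$genome_fna, cfg$gff3,
                                 cfg$proteome_faa, cfg$cds_fna)
    elements <- read_element_table(cfg$elements_tsv)
    expr <- if (!is.null(cfg$expression_tsv))
      read_expression_tsv(cfg$expression_tsv) else NULL
    refs <- NULL; ref_labels <- NULL; ref_clades <- NULL
    if (!is.null(cfg$refs_faa)) {
      refs <- read_fasta(cfg$refs_faa, "protein")
      lab <- read.delim(cfg$ref_labels_tsv, stringsAsFactors = FALSE)
      ref_labels <- setNames(lab$group, lab$ref_id)
      if ("clade" %in% names(lab)) ref_clades <- setNames(lab$clade, lab$ref_id)
    }

    stage <- "identify"
    profiles <- lapply(seq_along(cfg$domain_consensus), function(i)
      build_profile(seed_alignment_variants(cfg$domain_consensus[[i]],
                                            seed = sub_seed(cfg$seed,
                                                            "profiles")),
                    name = names(cfg$domain_consensus)[i]))
    names(profiles) <- names(cfg$domain_consensus)
    members <- identify_family(bundle, profiles, cfg$threshold_frac)
    write.table(members[, setdiff(names(members), "exons")],
                file.path(out, "members.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    member_ids <- members$gene_id
    report$n_members <- length(member_ids)

    stage <- "phylogeny"
    assignments <- NULL
    if (!is.null(refs) && length(member_ids) >= 2L) {
      seqs <- c(bundle$proteome[member_ids], refs)
      aln <- progressive_msa(seqs)
      D <- distance_matrix(aln, model = cfg$distance_model)
      boot <- if (cfg$bootstrap_reps > 0L)
        list(alignment = aln, n_reps = cfg$bootstrap_reps,
             seed = sub_seed(cfg$seed, "bootstrap"),
             model = cfg$distance_model) else NULL
      tree <- nj_tree(D, bootstrap = boot)
      write_newick(tree, file.path(out, "tree.nwk"))
      assignments <- assign_subfamilies(tree, ref_labels)
      write.table(assignments, file.path(out, "assignments.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$group_counts <- as.list(table(assignments$group))
      if (!is.null(ref_clades)) {
        groups <- c(setNames(assignments$group, assignments$member),
                    ref_labels)
        clades <- c(setNames(rep(cfg$member_clade, nrow(assignments)),
                             assignments$member), ref_clades)
        comp <- subfamily_composition(groups, clades)
        write.table(comp, file.path(out, "composition.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        report$composition <- comp
      }
    }

    stage <- "gene_structure"
    gs <- do.call(rbind, lapply(member_ids, function(id) {
      ex <- bundle$genes[id, "exons"][[1L]]
      data.frame(gene_id = id, n_exons = nrow(ex),
                 exon_lengths = paste(ex[, 2L] - ex[, 1L], collapse = ","),
                 gene_span = bundle$genes[id, "end"] - bundle$genes[id, "start"],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(gs))
      write.table(gs, file.path(out, "gene_structure.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    report$exon_count_range <- if (is.null(gs)) NULL else range(gs$n_exons)

    stage <- "evolution"
    hits_all <- similarity_search(bundle$proteome, bundle$proteome,
                                  min_score = cfg$min_score, top_n = cfg$top_n)
    ranks <- setNames(bundle$genes$rank, bundle$genes$gene_id)
    chroms <- setNames(bundle$genes$chrom, bundle$genes$gene_id)
    anchors <- data.frame(gene_a = hits_all$query_id,
                          gene_b = hits_all$subject_id,
                          chrom_a = chroms[hits_all$query_id],
                          rank_a = ranks[hits_all$query_id],
                          chrom_b = chroms[hits_all$subject_id],
                          rank_b = ranks[hits_all$subject_id],
                          stringsAsFactors = FALSE)
    # each undirected anchor once, and only one chromosome-pair orientation
    keep <- anchors$chrom_a < anchors$chrom_b |
      (anchors$chrom_a == anchors$chrom_b & anchors$rank_a < anchors$rank_b)
    blocks <- chain_blocks(anchors[keep, , drop = FALSE],
                           min_anchors = cfg$min_anchors,
                           max_gap = cfg$max_gap)
    member_hits <- hits_all[hits_all$query_id %in% member_ids &
                              hits_all$subject_id %in% member_ids, ,
                            drop = FALSE]
    dups <- classify_duplications(members, member_hits, blocks,
                                  tandem_max_gap = cfg$tandem_max_gap)
    write.table(dups, file.path(out, "duplications.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$duplications_by_type <- as.list(table(dups$dup_type))
    kaks_rows <- lapply(seq_len(nrow(dups)), function(i) {
      res <- pair_kaks(bundle, dups$gene_a[i], dups$gene_b[i])
      data.frame(gene_a = dups$gene_a[i], gene_b = dups$gene_b[i],
                 dup_type = dups$dup_type[i], Ka = res$Ka, Ks = res$Ks,
                 KaKs = res$ratio, selection = res$selection,
                 n_codons = res$n_codons_used, stringsAsFactors = FALSE)
    })
    kaks <- if (length(kaks_rows)) do.call(rbind, kaks_rows) else
      data.frame(gene_a = character(), gene_b = character(),
                 dup_type = character(), Ka = numeric(), Ks = numeric(),
                 KaKs = numeric(), selection = character(),
                 n_codons = integer())
    write.table(kaks, file.path(out, "kaks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$kaks_summary <- if (nrow(kaks)) list(
      n_pairs = nrow(kaks),
      n_purifying = sum(kaks$selection == "purifying"),
      max_ratio = max(kaks$KaKs, na.rm = TRUE),
      median_ratio = median(kaks$KaKs, na.rm = TRUE)) else
        list(n_pairs = 0L)

    stage <- "regulation"
    promoters <- extract_promoters(bundle, member_ids,
                                   length = cfg$promoter_length)
    write_fasta(setNames(promoters$seq, promoters$gene_id),
                file.path(out, "promoters.fna"))
    el_hits <- scan_elements(promoters, elements)
    write.table(el_hits, file.path(out, "element_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    census <- summarize_categories(el_hits, elements)
    write.table(census$by_category, file.path(out, "element_census.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!census$empty)
      write.table(data.frame(gene_id = rownames(census$per_gene),
                             census$per_gene, check.names = FALSE),
                  file.path(out, "per_gene_elements.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    report$element_total <- census$total
    report$element_types <- census$n_types
    report$category_pct <- setNames(as.list(round(census$by_category$pct, 2)),
                                    census$by_category$category)

    stage <- "expression"
    if (!is.null(expr)) {
      mem_expr <- expr[intersect(rownames(expr), member_ids), , drop = FALSE]
      calls <- classify_expression(mem_expr,
                                   expressed_fpkm = cfg$expressed_fpkm,
                                   tau_specific = cfg$tau_specific)
      write.table(calls, file.path(out, "expr_calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_expression_tsv(log2_transform(mem_expr),
                           file.path(out, "log2_matrix.tsv"))
      report$expression_calls <- as.list(table(calls$call))
    }

    stage <- "report"
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }, error = on_fail)
  invisible(report)
}
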
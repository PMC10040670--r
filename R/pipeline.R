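#' Read a protein FASTA into a named character vector
#'
#' Thin wrapper over \code{seqinr::read.fasta}.
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_proteins <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  toupper(unlist(fa))
}

.parse_gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read gene loci (and transcript models) from a GFF3 file
#'
#' @param path GFF3 path.
#' @return A list with \code{genes} (data.frame gene_id, chrom, start, end,
#'   strand, rank — rank being the gene's order by start on its chromosome)
#'   and \code{transcripts} (data.frame transcript_id, gene_id, exon
#'   count bookkeeping via \code{exons}, a list-column of exon start
#'   matrices).
#' @export
read_gene_models <- function(path) {
  gff <- ape::read.gff(path)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  gdf <- data.frame(gene_id = .parse_gff_attr(genes$attributes, "ID"),
                    chrom = as.character(genes$seqid),
                    start = genes$start, end = genes$end,
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  gdf <- gdf[order(gdf$chrom, gdf$start), , drop = FALSE]
  gdf$rank <- stats::ave(gdf$start, gdf$chrom, FUN = seq_along)
  mrna <- gff[gff$type == "mRNA", , drop = FALSE]
  exon <- gff[gff$type == "exon", , drop = FALSE]
  tx <- data.frame(transcript_id = .parse_gff_attr(mrna$attributes, "ID"),
                   gene_id = .parse_gff_attr(mrna$attributes, "Parent"),
                   stringsAsFactors = FALSE)
  exon_parent <- .parse_gff_attr(exon$attributes, "Parent")
  tx$exons <- lapply(tx$transcript_id, function(tid) {
    e <- exon[exon_parent == tid, c("start", "end"), drop = FALSE]
    e[order(e$start), , drop = FALSE]
  })
  list(genes = gdf, transcripts = tx)
}

## transcripts of a gene, marking which contain the gene's first exon
## (5'-most on + strand, 3'-coordinate-most on - strand)
.ppdk_model_from_gff <- function(models, gene_id, strand) {
  tx <- models$transcripts[models$transcripts$gene_id == gene_id, ,
                           drop = FALSE]
  if (nrow(tx) == 0) return(NULL)
  all_exons <- unique(do.call(rbind, tx$exons))
  ## order exons 5' to 3' so the biological first exon has index 1
  ord <- order(if (identical(strand, "-")) -all_exons$start else
                 all_exons$start)
  all_exons <- all_exons[ord, , drop = FALSE]
  txs <- lapply(seq_len(nrow(tx)), function(i) {
    e <- tx$exons[[i]]
    sort(match(paste(e$start, e$end),
               paste(all_exons$start, all_exons$end)))
  })
  names(txs) <- sub("^.*\\.", "", tx$transcript_id)
  list(gene_id = gene_id, exons = as.data.frame(all_exons),
       transcripts = txs)
}

#' Run the full classification pipeline on a scenario directory
#'
#' Stages: screening (BLAST + domain filters per family), phylogeny (JTT
#' NJ tree with bootstrap, orthogroup cutting, C4-orthogroup identification
#' via per-family anchor genes), diagnostics and protein features
#' (diagnostic sites, MDH coenzyme typing, cTP/localization evidence),
#' expression (FPKM, EL, leaf-dominance calls), genome context (tandem
#' arrays, promoter element scan), and classification. Every stage writes a
#' TSV under \code{out_dir}; a JSON manifest records the seed and input
#' checksums so reruns on identical inputs are byte-identical.
#'
#' @param paths Named list of input files as produced by
#'   \code{\link{generate_scenario}} (fields \code{aln_<family>},
#'   \code{blast_<family>}, \code{domtbl_<family>}, \code{genome},
#'   \code{gff}, \code{counts}, \code{gene_lengths}, \code{lib_sizes},
#'   \code{ctp}, \code{localization}).
#' @param anchors Named character vector: per family, a known C4 reference
#'   gene; the orthogroup containing it is the family's C4 orthogroup.
#' @param out_dir Output directory.
#' @param replicates Bootstrap replicates per family tree.
#' @param seed Seed for the bootstrap resampling.
#' @param min_support,max_copies Orthogroup cutting parameters.
#' @param el_min,fpkm_min Leaf-dominance thresholds.
#' @param max_intervening Tandem rank-gap threshold.
#' @param pepc_ser_col,mdh_coenzyme_col Alignment columns (identity mapping)
#'   of the PEPC C-terminal serine site and the MDH coenzyme site.
#' @return Invisibly, a list with \code{calls} (data.frame), \code{members},
#'   \code{orthogroups}, \code{leaf_calls}, \code{arrays}, \code{files}.
#' @export
run_pipeline <- function(paths, anchors, out_dir = tempfile(),
                         replicates = 100, seed = 1, min_support = 50,
                         max_copies = 1, el_min = 40, fpkm_min = 1,
                         max_intervening = 5, pepc_ser_col = 80,
                         mdh_coenzyme_col = 43) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  families <- sub("^aln_", "", grep("^aln_", names(paths), value = TRUE))

  ## --- screening -----------------------------------------------------
  members <- list()
  for (fam in families) {
    spec <- family_spec(fam)
    hits <- read_blast_tabular(paths[[paste0("blast_", fam)]])
    doms <- read_hmmer_domtbl(paths[[paste0("domtbl_", fam)]])
    out <- write_family_members(hits, doms, spec,
                                file.path(out_dir, paste0("members_", .fam_short[[fam]], ".tsv")))
    members[[fam]] <- out$gene_id
  }

  ## --- phylogeny + orthogroups ---------------------------------------
  orthogroups <- list(); c4_members <- list()
  for (fam in families) {
    seqs <- read_fasta_proteins(paths[[paste0("aln_", fam)]])
    seqs <- seqs[names(seqs) %in% members[[fam]]]
    tree <- bootstrap_support(seqs, replicates = replicates, seed = seed)
    ape::write.tree(tree, file.path(out_dir, paste0("tree_", .fam_short[[fam]], ".nwk")))
    species_of <- setNames(sub("_.*$", "", names(seqs)), names(seqs))
    cut <- cut_orthogroups(tree, species_of, min_support = min_support,
                           max_copies = max_copies)
    orthogroups[[fam]] <- cut
    anchor <- anchors[[fam]]
    in_anchor_group <- vapply(cut$groups, function(g) anchor %in% g,
                              logical(1))
    c4_members[[fam]] <- if (any(in_anchor_group))
      cut$groups[[which(in_anchor_group)[1]]] else character(0)
  }
  og_rows <- do.call(rbind, lapply(families, function(fam) {
    cut <- orthogroups[[fam]]
    if (length(cut$groups) == 0) return(NULL)
    do.call(rbind, lapply(names(cut$groups), function(og)
      data.frame(family = fam, orthogroup = og,
                 gene_id = cut$groups[[og]], stringsAsFactors = FALSE)))
  }))
  utils::write.table(og_rows, file.path(out_dir, "orthogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- expression -----------------------------------------------------
  have_expression <- !is.null(paths$counts) && file.exists(paths$counts)
  if (have_expression) {
    counts_df <- utils::read.delim(paths$counts, check.names = FALSE)
    counts <- as.matrix(counts_df[, -1, drop = FALSE])
    rownames(counts) <- counts_df[[1]]
    lens <- utils::read.delim(paths$gene_lengths)
    lengths <- setNames(lens$length, lens$gene_id)
    libs <- utils::read.delim(paths$lib_sizes)
    lib_sizes <- setNames(libs$mapped_fragments, libs$tissue)
    fpkm_mat <- fpkm(counts, lengths, lib_sizes)
    em <- el_matrix(fpkm_mat)
    lc <- leaf_calls(fpkm_mat, el_min = el_min, fpkm_min = fpkm_min)
    utils::write.table(data.frame(gene_id = rownames(em$el),
                                  round(em$el, 2), leaf_call = lc,
                                  check.names = FALSE),
                       file.path(out_dir, "el_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    warning("no expression matrix provided: leaf-dominance evidence is ",
            "unknown and calls will be indeterminate where it is required")
    fpkm_mat <- NULL
    lc <- character(0)
  }

  ## --- protein features ----------------------------------------------
  ctp_ann <- utils::read.delim(paths$ctp)
  loc_ann <- utils::read.delim(paths$localization)
  localization_of <- function(g) {
    i <- match(g, loc_ann$gene_id)
    if (!is.na(i)) return(as.character(loc_ann$localization[i]))
    ev <- ctp_evidence(g, ctp_ann)
    switch(ev$has_ctp, yes = "chloroplast", no = "cytoplasm", "unknown")
  }

  ## --- genome context --------------------------------------------------
  models <- read_gene_models(paths$gff)
  fam_of <- do.call(rbind, lapply(families, function(fam)
    data.frame(gene_id = members[[fam]], family = fam,
               stringsAsFactors = FALSE)))
  loci <- merge(models$genes, fam_of, by = "gene_id")
  arrays <- detect_tandem(loci, max_intervening = max_intervening)
  tandem_genes <- unlist(arrays)
  genome <- read_fasta_proteins(paths$genome)   # plain sequences; DNA here
  defs <- builtin_elements()
  hit_rows <- list()
  for (i in seq_len(nrow(loci))) {
    prom <- extract_promoter(genome, loci[i, ])
    hit_rows[[i]] <- scan_elements(prom, defs, gene_id = loci$gene_id[i])
  }
  hits <- do.call(rbind, hit_rows)
  utils::write.table(hits, file.path(out_dir, "element_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- classification --------------------------------------------------
  all_seqs <- unlist(lapply(families, function(fam) {
    s <- read_fasta_proteins(paths[[paste0("aln_", fam)]])
    s[names(s) %in% members[[fam]]]
  }))
  leaf_of <- function(id) if (id %in% names(lc)) lc[[id]] else NA_character_
  identity_map <- function(n) data.frame(ref_pos = seq_len(n),
                                         query_pos = seq_len(n))
  bundles <- list()
  for (fam in families) {
    for (g in members[[fam]]) {
      strand <- loci$strand[match(g, loci$gene_id)]
      model <- if (fam == "PPDK") .ppdk_model_from_gff(models, g, strand)
               else NULL
      if (!is.null(model) && length(model$transcripts) > 1) {
        tx_calls <- setNames(vapply(names(model$transcripts), function(tx)
          leaf_of(paste0(g, ".", tx)), ""), names(model$transcripts))
        iso <- ppdk_isoforms(model, tx_calls)
        for (k in seq_len(nrow(iso))) {
          bundles[[paste0(g, ".", iso$transcript[k])]] <- evidence_bundle(
            paste0(g, ".", iso$transcript[k]), "PPDK",
            leaf_call = iso$leaf_call[k],
            localization = iso$isoform[k],
            tandem = g %in% tandem_genes)
        }
        next
      }
      seq <- all_seqs[[g]]
      diag <- NA_character_
      coen <- "n/a"
      if (fam == "PEPC") {
        rep_site <- check_known_sites(
          seq, identity_map(nchar(seq)),
          data.frame(site_id = "ser", position = pepc_ser_col,
                     c4_states = "S", c3_states = "A"))
        diag <- rep_site$call[1]
      }
      if (fam == "MDH")
        coen <- mdh_coenzyme_type(seq, mdh_coenzyme_col)
      max_leaf <- NA
      if (fam == "RbcS" && have_expression) {
        sp <- sub("_.*$", "", g)
        fam_sp <- members[[fam]][startsWith(members[[fam]], paste0(sp, "_"))]
        leaf_fpkm <- fpkm_mat[fam_sp, "leaf"]
        best <- fam_sp[order(-leaf_fpkm, fam_sp)][1]
        max_leaf <- identical(g, best)
      }
      bundles[[g]] <- evidence_bundle(
        g, fam,
        c4_orthogroup = g %in% c4_members[[fam]],
        leaf_call = leaf_of(g),
        localization = localization_of(g),
        diag_site = diag, coenzyme = coen,
        max_leaf_fpkm = max_leaf,
        tandem = g %in% tandem_genes,
        orthogroup = {
          r <- og_rows[og_rows$gene_id == g & og_rows$family == fam, ]
          if (nrow(r)) r$orthogroup[1] else NA_character_
        })
    }
  }
  calls <- classify_all(bundles, file.path(out_dir, "c4_calls.tsv"))

  manifest <- list(
    package = as.character(utils::packageVersion("c4ortho")),
    seed = seed,
    inputs = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(calls = calls, members = members,
                 orthogroups = orthogroups, c4_members = c4_members,
                 leaf_calls = lc, arrays = arrays, element_hits = hits,
                 fpkm = fpkm_mat, out_dir = out_dir))
}

#' Roll up per-family, per-species gene counts in the screening-table layout
#'
#' @param membership Data.frame with columns \code{family} and
#'   \code{species} (one row per gene).
#' @return A data.frame: one row per family plus a Total row, one column per
#'   species plus a total column.
#' @export
summarize_counts <- function(membership) {
  if (nrow(membership) == 0)
    return(data.frame(family = "Total", total = 0))
  grid <- as.data.frame.matrix(table(membership$family, membership$species))
  ## canonical family order (the six-enzyme layout), extras appended
  fams <- rownames(grid)
  ord <- c(intersect(C4_FAMILIES, fams), sort(setdiff(fams, C4_FAMILIES)))
  grid <- grid[ord, , drop = FALSE]
  grid <- cbind(family = rownames(grid), grid, total = rowSums(grid))
  rownames(grid) <- NULL
  totals <- c(family = "Total",
              as.list(colSums(grid[, -1, drop = FALSE])))
  rbind(grid, as.data.frame(totals, check.names = FALSE))
}

#' Summary report over pipeline outputs
#'
#' Counts per family and species in the screening-table layout, tandem
#' percentages per family, and mean element counts per group and bin.
#'
#' @param result The list returned by \code{\link{run_pipeline}}.
#' @return A list with \code{counts}, \code{tandem} (per-family
#'   \code{\link{tandem_summary}} results), and \code{calls_by_label}.
#' @export
summarize_results <- function(result) {
  membership <- do.call(rbind, lapply(names(result$members), function(fam)
    if (length(result$members[[fam]]))
      data.frame(family = fam,
                 species = sub("_.*$", "", result$members[[fam]]),
                 stringsAsFactors = FALSE)))
  tandem <- lapply(names(result$members), function(fam)
    if (length(result$members[[fam]]))
      tandem_summary(result$members[[fam]], result$arrays))
  names(tandem) <- names(result$members)
  list(counts = summarize_counts(membership),
       tandem = tandem,
       calls_by_label = table(result$calls$label))
}
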
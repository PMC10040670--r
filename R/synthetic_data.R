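#' Default synthetic scenario configuration
#'
#' Describes a five-species grass panel (three C4: maize Zm, sorghum Sb,
#' foxtail millet Si; two C3: rice Os, wheat Ta) carrying all six enzyme
#' families, with one designated C4 orthogroup per family, planted
#' diagnostic residues, chloroplast transit peptides, tandem arrays,
#' promoter cis-elements, and negative-binomial tissue expression with a
#' 20-fold leaf induction of C4 copies.
#'
#' @param seed Integer seed; fully determines the generated data.
#' @param leaf_fold Leaf FPKM fold-up of C4 copies over their other tissues.
#' @param base_fpkm Baseline per-tissue FPKM of C4 copies outside the leaf.
#' @param dispersion Negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2).
#' @param protein_length Simulated protein length (alignment columns).
#' @param t_deep,t_shallow Branch lengths (substitutions/site) separating
#'   orthogroups and, within an orthogroup, species copies.
#' @param n_orthogroups Named integer vector of orthogroup counts per family.
#' @param c4_orthogroup Named character vector naming each family's C4
#'   orthogroup.
#' @param max_intervening Tandem rank-gap parameter the truth is built for.
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(seed = 1, leaf_fold = 20, base_fpkm = 10,
                            dispersion = 0.1, protein_length = 120,
                            t_deep = 0.7, t_shallow = 0.08,
                            n_orthogroups = c("beta-CA" = 3, "RbcS" = 3,
                                              "PEPC" = 4, "NADP-ME" = 4,
                                              "MDH" = 4, "PPDK" = 2),
                            c4_orthogroup = c("beta-CA" = "og3",
                                              "RbcS" = "og3",
                                              "PEPC" = "og4",
                                              "NADP-ME" = "og4",
                                              "MDH" = "og3",
                                              "PPDK" = "og1"),
                            max_intervening = 5) {
  if (leaf_fold < 1) stop("leaf fold-change must be >= 1")
  if (any(n_orthogroups < 1)) stop("all orthogroup counts must be >= 1")
  species <- data.frame(
    code = c("Zm", "Sb", "Si", "Os", "Ta"),
    name = c("maize", "sorghum", "foxtail_millet", "rice", "wheat"),
    type = c("C4", "C4", "C4", "C3", "C3"),
    stringsAsFactors = FALSE)
  structure(list(seed = seed, species = species, leaf_fold = leaf_fold,
                 base_fpkm = base_fpkm, dispersion = dispersion,
                 protein_length = protein_length, t_deep = t_deep,
                 t_shallow = t_shallow, n_orthogroups = n_orthogroups,
                 c4_orthogroup = c4_orthogroup,
                 max_intervening = max_intervening,
                 tissues = c("root", "shoot", "spike", "leaf"),
                 pepc_ser_col = 80L, mdh_coenzyme_col = 43L,
                 ctp_leader_len = 50L, promoter_length = 2000L),
            class = "scenario_config")
}

#' Evolve a protein sequence for time t under the JTT model
#'
#' Per-site multinomial draw from the JTT transition probabilities; used by
#' the generator so that estimated JTT distances can be checked against the
#' planted branch lengths.
#'
#' @param seq Residue character vector (or string).
#' @param t Branch length in substitutions/site.
#' @return Residue character vector of the same length.
#' @export
evolve_jtt <- function(seq, t) {
  s <- .as_residue_vector(seq)
  P <- jtt_prob_matrix(t)
  idx <- match(s, AA_ALPHABET)
  vapply(idx, function(i) sample(AA_ALPHABET, 1, prob = P[i, ]), "")
}

#' Draw a random protein from the JTT stationary distribution
#'
#' @param length Number of residues.
#' @return Residue character vector.
#' @export
random_jtt_protein <- function(length) {
  freqs <- JTT_FREQUENCIES / sum(JTT_FREQUENCIES)
  sample(AA_ALPHABET, length, replace = TRUE, prob = freqs)
}

#' Simulate negative-binomial expression counts from planted FPKM profiles
#'
#' Expected counts are mu = FPKM * (length/1000) * (library/1e6); counts are
#' drawn NB with variance mu + dispersion * mu^2 (dispersion 0 = Poisson).
#'
#' @param profiles Genes x tissues matrix of planted FPKM means.
#' @param lengths Named per-gene lengths (bp).
#' @param lib_sizes Named per-tissue library sizes.
#' @param dispersion NB dispersion (>= 0).
#' @param seed Integer seed.
#' @return Integer count matrix with the profile dimnames.
#' @export
simulate_expression <- function(profiles, lengths, lib_sizes,
                                dispersion = 0.1, seed = 1) {
  if (dispersion < 0) stop("negative dispersion")
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("planted FPKM means must be >= 0")
  set.seed(seed)
  mu <- sweep(sweep(profiles, 1, lengths[rownames(profiles)] / 1000, "*"),
              2, lib_sizes[colnames(profiles)] / 1e6, "*")
  counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  for (j in seq_len(ncol(mu))) {
    counts[, j] <- if (dispersion == 0) stats::rpois(nrow(mu), mu[, j])
    else stats::rnbinom(nrow(mu), mu = mu[, j], size = 1 / dispersion)
  }
  counts
}

## ---- promoter construction -------------------------------------------

.instantiate_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) sample(IUPAC_DNA[[ch]], 1), ""),
        collapse = "")
}

.scrub_patterns <- function(seq, patterns, max_iter = 10000) {
  for (iter in seq_len(max_iter)) {
    hit <- NULL
    for (p in patterns) {
      rx <- .iupac_regex(p)
      m <- regexpr(rx, seq, perl = TRUE)
      if (m != -1) { hit <- c(as.integer(m), nchar(p)); break }
      mrc <- regexpr(rx, .revcomp(seq), perl = TRUE)
      if (mrc != -1) {
        hit <- c(nchar(seq) - (as.integer(mrc) + nchar(p) - 1) + 1, nchar(p))
        break
      }
    }
    if (is.null(hit)) return(seq)
    pos <- hit[1] + sample.int(hit[2], 1) - 1
    old <- substr(seq, pos, pos)
    substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  stop("could not scrub promoter background")
}

#' Build a promoter with an exact planted element content
#'
#' Generates a random background, removes every chance match of the element
#' patterns (both strands), then inserts the requested number of concrete
#' motif instances per upstream bin at non-overlapping positions. The
#' returned promoter therefore contains exactly the planted matches.
#'
#' @param plan Data.frame with columns \code{element}, \code{bin} (one of
#'   "(-1..-1000)", "(-1001..-2000)"), \code{n}.
#' @param defs Element definitions (see \code{\link{builtin_elements}}).
#' @param length Promoter length (>= 2000 for both bins to exist).
#' @return Promoter string with attribute \code{planted} (data.frame of
#'   element, offset).
#' @export
make_promoter <- function(plan, defs = builtin_elements(), length = 2000) {
  for (attempt in 1:20) {
    bg <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                collapse = "")
    bg <- .scrub_patterns(bg, defs$pattern)
    used <- integer(0)
    planted <- list()
    ok <- TRUE
    if (nrow(plan)) for (i in seq_len(nrow(plan))) {
      def <- defs[defs$element == plan$element[i], , drop = FALSE]
      if (nrow(def) != 1) stop("unknown element in plan: ", plan$element[i])
      w <- nchar(def$pattern)
      lo_off <- if (plan$bin[i] == "(-1..-1000)") -1000L else -2000L
      hi_off <- if (plan$bin[i] == "(-1..-1000)") -1L else -1001L
      n_i <- plan$n[i]
      if (n_i == 0) next
      for (k in seq_len(n_i)) {
        placed <- FALSE
        for (try in 1:200) {
          off <- sample(seq(lo_off, hi_off - w + 1L), 1)
          pos <- length + off + 1L          # 1-based start in promoter
          span <- pos:(pos + w - 1L)
          if (any(span %in% used) || any(span > length) || any(span < 1)) next
          substr(bg, pos, pos + w - 1L) <- .instantiate_iupac(def$pattern)
          used <- c(used, (min(span) - w + 1L):(max(span) + w - 1L))
          planted[[base::length(planted) + 1L]] <-
            data.frame(element = def$element, offset = off)
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    ## insertion junctions can create new chance matches; verify and retry
    hits <- scan_elements(bg, defs)
    want <- if (nrow(plan)) sum(plan$n) else 0L
    if (nrow(hits) == want) {
      attr(bg, "planted") <- if (base::length(planted))
        do.call(rbind, planted) else data.frame(element = character(0),
                                                offset = integer(0))
      return(bg)
    }
  }
  stop("could not build promoter with exact planted content")
}

## ---- whole-scenario generation ---------------------------------------

.fam_short <- c("beta-CA" = "CA", "RbcS" = "RbcS", "PEPC" = "PEPC",
                "NADP-ME" = "ME", "MDH" = "MDH", "PPDK" = "PPDK")

#' Generate a complete synthetic study scenario with planted ground truth
#'
#' Emits, under \code{out_dir}: per-family protein FASTA alignments
#' (indel-free simulation along a two-level orthogroup/species tree under
#' the JTT model, so sequences are already aligned), a genome FASTA and a
#' GFF3 with family and filler genes (tandem arrays and planted promoter
#' elements included), BLAST-tabular and HMMER domtblout screening inputs
#' with decoy genes, tissue count matrices (negative binomial) with gene
#' lengths and library sizes, and cTP/localization annotation tables. The
#' returned ground truth records every planted label.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with \code{truth} (per-gene data.frame),
#'   \code{files} (named paths), \code{anchors} (per-family known C4
#'   reference gene), and \code{planted_elements}.
#' @export
generate_scenario <- function(cfg = scenario_config(), out_dir = tempfile()) {
  stopifnot(inherits(cfg, "scenario_config"))
  n_c4_species <- sum(cfg$species$type == "C4")
  if (n_c4_species < 1) stop("inconsistent config: no C4 species")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  species <- cfg$species
  tissues <- cfg$tissues
  families <- names(cfg$n_orthogroups)

  truth <- list(); proteins <- list(); fam_files <- list()
  blast <- list(); domtbl <- list()

  for (fam in families) {
    short <- .fam_short[[fam]]
    ogs <- paste0("og", seq_len(cfg$n_orthogroups[[fam]]))
    c4_og <- cfg$c4_orthogroup[[fam]]
    root <- random_jtt_protein(cfg$protein_length)
    fam_seqs <- list()
    for (og in ogs) {
      anc <- evolve_jtt(root, cfg$t_deep)
      for (si in seq_len(nrow(species))) {
        sp <- species$code[si]
        gene <- paste0(sp, "_", short, "_", og)
        seq <- evolve_jtt(anc, cfg$t_shallow)
        is_c4 <- og == c4_og && species$type[si] == "C4"
        ## chloroplast copies get an S/T-rich, acid-poor N-terminal leader
        chloro <- (fam %in% c("NADP-ME", "MDH") && og == c4_og) ||
          (fam == "PPDK" && og == "og1") ||
          (fam == "beta-CA" && og == c4_og && species$type[si] == "C3")
        if (chloro) {
          lead <- sample(c("S", "T", "A", "L", "P", "R"),
                         cfg$ctp_leader_len, replace = TRUE,
                         prob = c(0.3, 0.15, 0.2, 0.15, 0.1, 0.1))
          seq[seq_len(cfg$ctp_leader_len)] <- lead
        }
        ## planted diagnostic residues (after any leader so they survive)
        if (fam == "PEPC")
          seq[cfg$pepc_ser_col] <- if (og == c4_og) "S" else "A"
        if (fam == "MDH")
          seq[cfg$mdh_coenzyme_col] <- if (og == c4_og) "G" else "D"
        fam_seqs[[gene]] <- seq
        loc <- if (chloro) "chloroplast"
               else if (fam == "MDH") "mitochondrion" else "cytoplasm"
        truth[[gene]] <- data.frame(
          gene_id = gene, species = sp, type = species$type[si],
          family = fam, orthogroup = og, is_c4 = is_c4,
          localization = loc,
          coenzyme = if (fam != "MDH") "n/a" else if (og == c4_og) "NADP" else "NAD",
          has_ctp = chloro, stringsAsFactors = FALSE)
      }
    }
    proteins[[fam]] <- fam_seqs

    ## screening inputs: true members hit the family reference strongly;
    ## decoys fail on identity, E-value, or a missing required domain
    spec <- family_spec(fam)
    ref <- paste0("REF_", short)
    mk_hit <- function(g, ev, id) sprintf(
      "%s\t%s\t%.2f\t%d\t%d\t0\t1\t%d\t1\t%d\t%s\t%.1f",
      ref, g, id, cfg$protein_length, round(cfg$protein_length * (1 - id / 100)),
      cfg$protein_length, cfg$protein_length, format(ev, scientific = TRUE),
      200 - log10(ev + 1e-300))
    rows <- vapply(names(fam_seqs), function(g)
      mk_hit(g, 10^-stats::runif(1, 20, 60), stats::runif(1, 72, 95)), "")
    decoys <- paste0("Dec_", short, "_", 1:4)
    rows <- c(rows,
      mk_hit(decoys[1], 1e-30, 45),    # identity below 60
      mk_hit(decoys[2], 1e-3, 80),     # E-value above 1e-5
      mk_hit(decoys[3], 1e-5, 80),     # E-value exactly at the cutoff
      mk_hit(decoys[4], 1e-30, 80))    # passes BLAST, lacks a domain
    blast[[fam]] <- rows
    mk_dom <- function(g, acc) sprintf(
      paste0("%s -          %d %s_profile %s %d 1e-40 500.0 0.1 1 1 ",
             "1e-42 1e-41 400.0 0.1 1 %d 1 %d 1 %d 0.95"),
      g, cfg$protein_length, acc, paste0(acc, ".12"), cfg$protein_length,
      cfg$protein_length, cfg$protein_length, cfg$protein_length)
    dom_rows <- c("# synthetic domtblout", "#")
    for (g in names(fam_seqs))
      for (acc in spec$required_domains) dom_rows <- c(dom_rows, mk_dom(g, acc))
    for (g in decoys[1:3])
      for (acc in spec$required_domains) dom_rows <- c(dom_rows, mk_dom(g, acc))
    dom_rows <- c(dom_rows, mk_dom(decoys[4], spec$required_domains[1]),
                  "# [ok]")
    if (length(spec$required_domains) == 1)   # still must lack "every domain"
      dom_rows <- setdiff(dom_rows, mk_dom(decoys[4], spec$required_domains[1]))
    domtbl[[fam]] <- dom_rows
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  ## ---- genome layout: ranks, tandem arrays, strands, coordinates ------
  truth$chrom <- paste0(truth$species, "_chr1")
  truth$rank <- NA_integer_; truth$strand <- "+"
  truth$tandem <- FALSE
  gene_len <- 1200L
  layout <- list()
  for (sp in species$code) {
    idx <- which(truth$species == sp)
    genes <- truth$gene_id[idx]
    ## adjacency plan: beta-CA og2+og3 form a pair; the three RbcS copies a
    ## triple; everything else isolated by > max_intervening filler genes
    pair <- paste0(sp, "_CA_og", 2:3)
    triple <- paste0(sp, "_RbcS_og", 1:3)
    rest <- setdiff(genes, c(pair, triple))
    order_plan <- c(list(pair), list(triple), as.list(rest[order(rest)]))
    rank <- 0L
    for (block in order_plan) {
      rank <- rank + cfg$max_intervening + 3L    # filler gap between blocks
      for (g in block) {
        rank <- rank + 1L
        truth$rank[truth$gene_id == g] <- rank
      }
      if (length(block) > 1)
        truth$tandem[truth$gene_id %in% block] <- TRUE
    }
    layout[[sp]] <- rank + cfg$max_intervening + 3L   # total ranks incl. tail
  }
  ## coordinates: each rank slot is promoter + gene + spacer
  slot <- cfg$promoter_length + gene_len + 200L
  truth$start <- (truth$rank - 1L) * slot + cfg$promoter_length + 1L
  truth$end <- truth$start + gene_len - 1L
  minus <- which(seq_len(nrow(truth)) %% 4 == 0)
  truth$strand[minus] <- "-"
  ## for - strand genes the promoter is downstream of end; shift them left
  ## inside their slot so the upstream window still fits in the slot
  truth$start[minus] <- (truth$rank[minus] - 1L) * slot + 101L
  truth$end[minus] <- truth$start[minus] + gene_len - 1L

  ## ---- promoters and genome sequence ----------------------------------
  defs <- builtin_elements()
  genome <- lapply(species$code, function(sp)
    paste(sample(c("A", "C", "G", "T"), layout[[sp]] * slot + slot,
                 replace = TRUE), collapse = ""))
  names(genome) <- paste0(species$code, "_chr1")
  planted_elements <- list()
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    fam <- truth$family[i]
    ## CAAT-box density contrast for the carbonic anhydrase C4 orthogroup:
    ## C3-crop copies carry twice the distal-bin density of C4-crop copies
    if (fam == "beta-CA" && truth$orthogroup[i] == cfg$c4_orthogroup[["beta-CA"]]) {
      distal_n <- if (truth$type[i] == "C3") 4L else 2L
      plan <- data.frame(element = "CAAT-box",
                         bin = c("(-1..-1000)", "(-1001..-2000)"),
                         n = c(2L, distal_n))
    } else {
      plan <- data.frame(element = "CAAT-box",
                         bin = c("(-1..-1000)", "(-1001..-2000)"),
                         n = c(1L, 1L))
    }
    prom <- make_promoter(plan, defs, cfg$promoter_length)
    planted_elements[[g]] <- attr(prom, "planted")
    chrom <- truth$chrom[i]
    if (truth$strand[i] == "+") {
      from <- truth$start[i] - cfg$promoter_length
      substr(genome[[chrom]], from, truth$start[i] - 1L) <- prom
    } else {
      from <- truth$end[i] + 1L
      substr(genome[[chrom]], from, from + cfg$promoter_length - 1L) <-
        .revcomp(prom)
    }
  }

  ## ---- expression profiles -------------------------------------------
  rows <- list()
  profile_of <- function(i) {
    fam <- truth$family[i]; og <- truth$orthogroup[i]
    c4og <- cfg$c4_orthogroup[[fam]]
    b <- cfg$base_fpkm
    if (truth$is_c4[i])
      return(c(root = b / 5, shoot = b / 5, spike = b / 5,
               leaf = b / 5 * cfg$leaf_fold))
    if (og == c4og)                    # C4-orthologous copy in a C3 crop
      return(c(root = b, shoot = b / 2, spike = 4 * b, leaf = b / 5))
    switch(1L + (truth$rank[i] %% 3L),
           c(root = 4 * b, shoot = b, spike = b, leaf = b),
           c(root = b, shoot = b, spike = 4 * b, leaf = b),
           c(root = 2 * b, shoot = 2 * b, spike = 2 * b, leaf = 2 * b))
  }
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    if (truth$family[i] == "PPDK" && truth$orthogroup[i] == "og1") {
      ## dual promoter: chloroplast transcript t1 follows the gene's C4
      ## status; cytosolic t2 is spike-dominant in every species
      p1 <- if (truth$is_c4[i])
        c(root = cfg$base_fpkm / 5, shoot = cfg$base_fpkm / 5,
          spike = cfg$base_fpkm / 5,
          leaf = cfg$base_fpkm / 5 * cfg$leaf_fold)
      else c(root = cfg$base_fpkm, shoot = cfg$base_fpkm / 2,
             spike = 4 * cfg$base_fpkm, leaf = cfg$base_fpkm / 5)
      rows[[paste0(g, ".t1")]] <- p1
      rows[[paste0(g, ".t2")]] <- c(root = cfg$base_fpkm,
                                    shoot = cfg$base_fpkm,
                                    spike = 6 * cfg$base_fpkm,
                                    leaf = cfg$base_fpkm)
    } else {
      rows[[g]] <- profile_of(i)
    }
  }
  profiles <- do.call(rbind, rows)
  colnames(profiles) <- tissues
  lengths <- setNames(rep(3L * cfg$protein_length, nrow(profiles)),
                      rownames(profiles))
  lib_sizes <- setNames(rep(2e7, length(tissues)), tissues)
  counts <- simulate_expression(profiles, lengths, lib_sizes,
                                dispersion = cfg$dispersion,
                                seed = cfg$seed + 1L)

  ## ---- write files ----------------------------------------------------
  files <- list()
  for (fam in families) {
    short <- .fam_short[[fam]]
    fa <- file.path(out_dir, paste0("aln_", short, ".faa"))
    .write_fasta(vapply(proteins[[fam]], paste, "", collapse = ""), fa)
    files[[paste0("aln_", fam)]] <- fa
    bl <- file.path(out_dir, paste0("blast_", short, ".tsv"))
    writeLines(blast[[fam]], bl); files[[paste0("blast_", fam)]] <- bl
    dt <- file.path(out_dir, paste0("domtbl_", short, ".txt"))
    writeLines(domtbl[[fam]], dt); files[[paste0("domtbl_", fam)]] <- dt
  }
  files$genome <- file.path(out_dir, "genome.fa")
  .write_fasta(unlist(genome), files$genome, width = 80)
  files$gff <- file.path(out_dir, "genes.gff3")
  .write_scenario_gff(truth, layout, slot, gene_len, cfg, files$gff)
  files$counts <- file.path(out_dir, "counts.tsv")
  utils::write.table(data.frame(gene_id = rownames(counts), counts,
                                check.names = FALSE),
                     files$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$gene_lengths <- file.path(out_dir, "gene_lengths.tsv")
  utils::write.table(data.frame(gene_id = names(lengths), length = lengths),
                     files$gene_lengths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$lib_sizes <- file.path(out_dir, "lib_sizes.tsv")
  utils::write.table(data.frame(tissue = names(lib_sizes),
                                mapped_fragments = lib_sizes),
                     files$lib_sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$ctp <- file.path(out_dir, "ctp_annotation.tsv")
  utils::write.table(data.frame(gene_id = truth$gene_id,
                                has_ctp = ifelse(truth$has_ctp, "yes", "no"),
                                ctp_len = ifelse(truth$has_ctp,
                                                 cfg$ctp_leader_len, NA)),
                     files$ctp, sep = "\t", quote = FALSE, row.names = FALSE)
  files$localization <- file.path(out_dir, "localization.tsv")
  utils::write.table(truth[, c("gene_id", "localization")],
                     files$localization, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  anchors <- setNames(vapply(families, function(fam)
    paste0("Zm_", .fam_short[[fam]], "_", cfg$c4_orthogroup[[fam]]), ""),
    families)
  ## per-transcript truth for the dual-promoter genes
  ppdk1 <- truth$gene_id[truth$family == "PPDK" & truth$orthogroup == "og1"]
  truth_tx <- truth
  truth_tx$truth_unit <- truth_tx$gene_id
  truth_tx$truth_unit[truth_tx$gene_id %in% ppdk1] <-
    paste0(truth_tx$gene_id[truth_tx$gene_id %in% ppdk1], ".t1")
  invisible(list(truth = truth_tx, files = files, anchors = anchors,
                 planted_elements = planted_elements,
                 profiles = profiles, config = cfg))
}

.write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

.write_scenario_gff <- function(truth, layout, slot, gene_len, cfg, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    base <- sprintf("%s\tc4ortho_sim\t%%s\t%%d\t%%d\t.\t%s\t.\t%%s",
                    truth$chrom[i], truth$strand[i])
    lines <- c(lines, sprintf(base, "gene", truth$start[i], truth$end[i],
                              paste0("ID=", g, ";family=", truth$family[i])))
    if (truth$family[i] == "PPDK" && truth$orthogroup[i] == "og1") {
      ## two exons; t1 carries exon 1 (chloroplast), t2 starts in intron 1
      e1 <- c(truth$start[i], truth$start[i] + 299L)
      e2 <- c(truth$start[i] + 500L, truth$end[i])
      if (truth$strand[i] == "-") {    # exon 1 is at the 3'-coordinate end
        e1 <- c(truth$end[i] - 299L, truth$end[i])
        e2 <- c(truth$start[i], truth$end[i] - 500L)
      }
      for (tx in c("t1", "t2")) {
        tid <- paste0(g, ".", tx)
        span <- if (tx == "t1") range(c(e1, e2)) else range(e2)
        lines <- c(lines,
          sprintf(base, "mRNA", span[1], span[2],
                  paste0("ID=", tid, ";Parent=", g)),
          if (tx == "t1") sprintf(base, "exon", e1[1], e1[2],
                                  paste0("Parent=", tid)),
          sprintf(base, "exon", e2[1], e2[2], paste0("Parent=", tid)))
      }
    } else {
      tid <- paste0(g, ".t1")
      lines <- c(lines,
        sprintf(base, "mRNA", truth$start[i], truth$end[i],
                paste0("ID=", tid, ";Parent=", g)),
        sprintf(base, "exon", truth$start[i], truth$end[i],
                paste0("Parent=", tid)))
    }
  }
  ## filler genes occupy the remaining rank slots so genome-wide gene ranks
  ## are meaningful for tandem detection
  for (sp in names(layout)) {
    chrom <- paste0(sp, "_chr1")
    taken <- truth$rank[truth$species == sp]
    for (r in setdiff(seq_len(layout[[sp]]), taken)) {
      s <- (r - 1L) * slot + cfg$promoter_length + 1L
      lines <- c(lines, sprintf(
        "%s\tc4ortho_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s_filler_%d",
        chrom, s, s + gene_len - 1L, sp, r))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
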
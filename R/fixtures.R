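## Verbatim TSV transcriptions of the study's summary tables, shipped with
## the package and guarded against transcription drift by md5 checksums.
.FIXTURE_FILES <- c(
  table1 = "table1_family_counts.tsv",
  table2 = "table2_orthogroup_genes.tsv",
  table3 = "table3_protein_characteristics.tsv",
  table4 = "table4_rbcs_flanking_regions.tsv",
  table5 = "table5_pepc_flanking_regions.tsv")

.FIXTURE_MD5 <- c(
  table1 = "f45cddcdd56fe961462a307c0154715b",
  table2 = "bf1326cfd5c921402d0bf6a72e0d71b0",
  table3 = "d420378b21e18d685793acc598280405",
  table4 = "f29a6cd40442828ac1ebced00adf0363",
  table5 = "41615932dbfb941f8be12f6ddbe1af3d")

#' Load a transcribed summary-table fixture
#'
#' The six-family screening table (table1: per-species copy numbers plus
#' required Pfam/CDD domains, with a totals row), the orthogroup membership
#' grid (table2), the C4/C4-orthologous protein characteristics (table3),
#' and the two flanking-region comparison tables: the RbcS regions across
#' grass genera (table4, two regions per species with C3/C4 labels) and the
#' PEPC region across 65 species (table5). table4/table5 are returned both
#' as raw data.frames and parsed into \code{\link{parse_flank_table}}
#' ambiguity matrices. A checksum mismatch (edited fixture) is an error.
#'
#' @param name One of "table1" ... "table5".
#' @return table1/table2/table3: a data.frame. table4: a list with
#'   \code{raw}, \code{region1}, \code{region2} (ambiguity matrices).
#'   table5: a list with \code{raw} and \code{region}.
#' @export
load_paper_fixture <- function(name) {
  if (!name %in% names(.FIXTURE_FILES))
    stop("unknown fixture: ", name, " (expected ",
         paste(names(.FIXTURE_FILES), collapse = ", "), ")")
  path <- system.file("extdata", .FIXTURE_FILES[[name]], package = "c4ortho")
  if (!nzchar(path)) stop("fixture file not installed: ", .FIXTURE_FILES[[name]])
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.FIXTURE_MD5[[name]])))
    stop("checksum mismatch for ", .FIXTURE_FILES[[name]],
         ": fixture transcription has drifted")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .norm_label <- function(p) ifelse(grepl("^Facultative", p), "facultative", p)
  switch(name,
    table4 = {
      lab <- .norm_label(df$ptype)
      list(raw = df,
           region1 = parse_flank_table(data.frame(
             id = df$species, sequence = df$region1, label = lab)),
           region2 = parse_flank_table(data.frame(
             id = df$species, sequence = df$region2, label = lab)))
    },
    table5 = {
      lab <- .norm_label(df$ptype)
      list(raw = df,
           region = parse_flank_table(data.frame(
             id = df$species, sequence = df$region, label = lab)))
    },
    df)
}

#' Path to the synthetic SbCA3 stand-in sequence
#'
#' A 448-aa synthetic protein constructed so that its ExPASy-convention
#' average molecular weight and Bjellqvist isoelectric point equal the
#' values reported for SbCA3 (48986.93 Da, pI 8.74). It is NOT the real
#' KXG32970 sequence; it exists so the physicochemical calculators can be
#' checked against the reported values without a sequence download.
#'
#' @return A list with \code{path} and \code{sequence} (string).
#' @export
synthetic_sbca3 <- function() {
  path <- system.file("extdata", "synthetic_sbca3.fasta", package = "c4ortho")
  if (!nzchar(path)) stop("synthetic_sbca3.fasta not installed")
  lines <- readLines(path)
  seq <- paste(lines[!startsWith(lines, ">")], collapse = "")
  list(path = path, sequence = seq)
}
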
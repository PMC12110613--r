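# Reading and writing simple somatic mutation (SSM) files in the ICGC
# dialect: tab-separated, 1-based inclusive coordinates, "-" for the null
# allele. Sequence context is taken from embedded context5/context3 columns
# when present, else fetched from an indexed reference FASTA.

SSM_COLUMN_ALIASES <- list(
  sample_id  = c("sample_id", "icgc_sample_id", "sample", "submitted_sample_id"),
  chromosome = c("chromosome", "chr", "chrom"),
  start      = c("chromosome_start", "start", "position", "pos"),
  end        = c("chromosome_end", "end"),
  ref        = c("reference_genome_allele", "reference_allele", "ref", "mutated_from_allele"),
  alt        = c("mutated_to_allele", "mutated_allele", "alt", "tumor_allele")
)

resolve_ssm_columns <- function(nms) {
  out <- list()
  for (field in names(SSM_COLUMN_ALIASES)) {
    hit <- intersect(SSM_COLUMN_ALIASES[[field]], tolower(nms))
    if (length(hit) == 0L)
      stop("SSM file is missing a required column for '", field,
           "' (accepted names: ",
           paste(SSM_COLUMN_ALIASES[[field]], collapse = ", "), ")")
    out[[field]] <- nms[match(hit[1], tolower(nms))]
  }
  out
}

infer_kind <- function(ref, alt) {
  dplyr::case_when(
    ref == "-" & alt != "-"                      ~ "INS",
    alt == "-" & ref != "-"                      ~ "DEL",
    nchar(ref) == 1L & nchar(alt) == 1L          ~ "SNV",
    nchar(ref) == 2L & nchar(alt) == 2L          ~ "DNV",
    TRUE                                         ~ "OTHER"
  )
}

#' Read an SSM file into mutation records
#'
#' Parses a tab-separated simple somatic mutation file (ICGC dialect) into a
#' tibble of mutation records with sequence context. Context is taken from
#' `context5` / `context3` columns when the file carries them; otherwise a
#' reference FASTA (with one sequence per chromosome) must be supplied and
#' flanking windows are extracted from it. Malformed rows (unknown mutation
#' kind, equal alleles, non-ACGT context in the needed window, context
#' exceeding chromosome bounds) are dropped, tallied and reported in the
#' `skip_report` attribute rather than raising an error.
#'
#' @param path SSM TSV file.
#' @param fasta Optional path to a reference FASTA used when the file has no
#'   embedded context columns (requires the Biostrings package).
#' @param flank5,flank3 Minimum context window widths fetched from the FASTA.
#' @return Tibble of records with columns `sample_id`, `chromosome`,
#'   `position`, `ref`, `alt`, `kind`, `context5`, `context3`, and a
#'   `skip_report` attribute tallying dropped rows.
#' @export
read_ssm <- function(path, fasta = NULL, flank5 = 20L, flank3 = 30L) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  cols <- resolve_ssm_columns(names(raw))
  rec <- tibble::tibble(
    sample_id  = raw[[cols$sample_id]],
    chromosome = raw[[cols$chromosome]],
    position   = suppressWarnings(as.integer(raw[[cols$start]])),
    ref        = toupper(raw[[cols$ref]]),
    alt        = toupper(raw[[cols$alt]])
  )
  rec$kind <- infer_kind(rec$ref, rec$alt)

  has_context <- all(c("context5", "context3") %in% names(raw))
  if (has_context) {
    rec$context5 <- toupper(raw$context5)
    rec$context3 <- toupper(raw$context3)
  } else {
    if (is.null(fasta))
      stop("SSM file has no context5/context3 columns; a reference FASTA is required")
    ctx <- fasta_context(rec, fasta, flank5 = flank5, flank3 = flank3)
    rec$context5 <- ctx$context5
    rec$context3 <- ctx$context3
  }

  skip <- character(0)
  bad_pos <- is.na(rec$position)
  skip <- c(skip, rep("unparseable position", sum(bad_pos)))
  bad_kind <- rec$kind == "OTHER" & !bad_pos
  skip <- c(skip, rep("unsupported mutation kind", sum(bad_kind)))
  same <- !bad_pos & !bad_kind & rec$ref == rec$alt
  skip <- c(skip, rep("ref equals alt", sum(same)))
  keep <- !bad_pos & !bad_kind & !same
  allele_chars <- paste0(ifelse(rec$ref == "-", "", rec$ref),
                         ifelse(rec$alt == "-", "", rec$alt))
  bad_ctx <- keep & (is.na(rec$context5) | is.na(rec$context3) |
                       grepl("[^ACGT]", rec$context5) |
                       grepl("[^ACGT]", rec$context3) |
                       grepl("[^ACGT]", allele_chars))
  skip <- c(skip, rep("non-ACGT allele or context", sum(bad_ctx)))
  keep <- keep & !bad_ctx

  out <- rec[keep, , drop = FALSE]
  report <- if (length(skip) > 0) {
    tb <- table(skip)
    tibble::tibble(reason = names(tb), n = as.integer(tb))
  } else {
    tibble::tibble(reason = character(0), n = integer(0))
  }
  attr(out, "skip_report") <- report
  out
}

fasta_context <- function(rec, fasta, flank5 = 20L, flank3 = 30L) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("FASTA context retrieval requires the Biostrings package")
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  n <- nrow(rec)
  c5 <- c3 <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    chrom <- rec$chromosome[i]
    if (!chrom %in% names(genome) || is.na(rec$position[i])) next
    sq <- genome[[chrom]]
    len <- length(sq)
    pos <- rec$position[i]
    ev_len <- if (rec$ref[i] == "-") nchar(rec$alt[i]) else nchar(rec$ref[i])
    w3 <- max(flank3, 5L * ev_len)
    if (rec$kind[i] == "INS") {
      # anchored at the base after which insertion occurs
      from5 <- pos - flank5 + 1L
      to3 <- pos + w3
      if (from5 < 1L || to3 > len || pos < 1L) next
      c5[i] <- as.character(Biostrings::subseq(sq, from5, pos))
      c3[i] <- as.character(Biostrings::subseq(sq, pos + 1L, to3))
    } else {
      ref_end <- pos + nchar(rec$ref[i]) - 1L
      from5 <- pos - flank5
      to3 <- ref_end + w3
      if (from5 < 1L || to3 > len) next
      c5[i] <- as.character(Biostrings::subseq(sq, from5, pos - 1L))
      c3[i] <- as.character(Biostrings::subseq(sq, ref_end + 1L, to3))
    }
  }
  dropped <- is.na(c5) & !is.na(rec$position)
  if (any(dropped))
    warning(sum(dropped), " record(s) with context window exceeding chromosome bounds dropped")
  list(context5 = c5, context3 = c3)
}

#' Write mutation records as an SSM file
#'
#' Emits the ICGC-dialect TSV consumed by [read_ssm()], including the
#' embedded `context5` / `context3` columns so the file round-trips without a
#' reference FASTA.
#'
#' @param records Tibble of mutation records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ssm <- function(records, path) {
  out <- tibble::tibble(
    icgc_sample_id = records$sample_id,
    chromosome = records$chromosome,
    chromosome_start = records$position,
    chromosome_end = records$position +
      ifelse(records$ref == "-", 0L, nchar(records$ref) - 1L),
    reference_genome_allele = records$ref,
    mutated_to_allele = records$alt,
    context5 = records$context5,
    context3 = records$context3
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
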
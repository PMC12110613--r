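# Canonical mutation channel schemes (SBS96 / DBS78 / ID83) and the
# classifiers mapping single somatic events onto them.

DNA_BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over A/C/G/T.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "TTG"))
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Canonical channel labels for a scheme
#'
#' Returns the ordered channel labels used throughout the package:
#' 96 trinucleotide-context single-base substitution channels, 78 doublet
#' substitution channels, or 83 insertion/deletion channels. SBS96 labels are
#' ordered substitution-major (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`) with
#' 5' and 3' flanks each cycling A, C, G, T. ID83 labels follow the
#' `len:Del|Ins:C|T|R|M:bin` syntax with a 0-based bin index for homopolymer /
#' repeat channels and a 1-based homology length for microhomology channels.
#'
#' @param scheme One of `"SBS96"`, `"DBS78"`, `"ID83"`.
#' @return Character vector of channel labels (length 96, 78 or 83).
#' @export
channel_labels <- function(scheme = c("SBS96", "DBS78", "ID83")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    SBS96 = sbs96_labels(),
    DBS78 = dbs78_labels(),
    ID83  = id83_labels()
  )
}

sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    unlist(lapply(DNA_BASES, function(f5) {
      paste0(f5, "[", s, "]", DNA_BASES)
    }))
  }))
}

# COSMIC v3 doublet channels. Ten canonical reference doublets; palindromic
# references (AT, CG, GC, TA) keep one representative per reverse-complement
# orbit of the alternate doublet.
dbs78_table <- function() {
  list(
    AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
    AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
    CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
    CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
    CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
    GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
    TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
    TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
    TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
    TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG")
  )
}

dbs78_labels <- function() {
  tab <- dbs78_table()
  unlist(lapply(names(tab), function(ref) paste0(ref, ">", tab[[ref]])),
         use.names = FALSE)
}

id83_labels <- function() {
  c(
    paste0("1:Del:C:", 0:5),
    paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5),
    paste0("1:Ins:T:", 0:5),
    unlist(lapply(2:5, function(l) paste0(l, ":Del:R:", 0:5))),
    unlist(lapply(2:5, function(l) paste0(l, ":Ins:R:", 0:5))),
    "2:Del:M:1",
    paste0("3:Del:M:", 1:2),
    paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5)
  )
}

#' Classify single-base substitutions into SBS96 channels
#'
#' Labels are `X[R>A]Y` with the reference pyrimidine convention: when the
#' reference base is a purine the trinucleotide and the alternate allele are
#' reverse-complemented before labeling, so classification is strand
#' invariant.
#'
#' @param ref,alt Single reference / alternate bases (character vectors).
#' @param context5,context3 Flanking sequence immediately 5' / 3' of the
#'   substituted base; at least one base each.
#' @return Character vector of SBS96 channel labels.
#' @examples
#' classify_sbs("C", "A", "A", "A")  # "A[C>A]A"
#' classify_sbs("G", "T", "T", "C")  # "G[C>A]A"
#' @export
classify_sbs <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("classify_sbs() expects single-base substitutions (SNV records)")
  if (any(ref == alt)) stop("ref and alt must differ for an SNV")
  if (any(!ref %in% DNA_BASES | !alt %in% DNA_BASES))
    stop("SNV alleles must be A, C, G or T")
  if (any(nchar(context5) < 1L | nchar(context3) < 1L))
    stop("one base of 5' and 3' context is required")
  f5 <- substr(context5, nchar(context5), nchar(context5))
  f3 <- substr(context3, 1L, 1L)
  if (any(!c(f5, f3) %in% DNA_BASES))
    stop("flanking context must be A, C, G or T")
  purine <- !ref %in% PYRIMIDINES
  r <- ifelse(purine, comp_base(ref), ref)
  a <- ifelse(purine, comp_base(alt), alt)
  new_f5 <- ifelse(purine, comp_base(f3), f5)
  new_f3 <- ifelse(purine, comp_base(f5), f3)
  paste0(new_f5, "[", r, ">", a, "]", new_f3)
}

#' Classify doublet-base substitutions into DBS78 channels
#'
#' Non-canonical reference doublets are reverse-complemented (both alleles)
#' onto the ten canonical reference doublets; for palindromic references the
#' alternate doublet is mapped onto its orbit representative.
#'
#' @param ref,alt Two-base reference / alternate alleles.
#' @return Character vector of DBS78 channel labels.
#' @examples
#' classify_dbs("CC", "AA")  # "CC>AA"
#' classify_dbs("GG", "TT")  # "CC>AA"
#' @export
classify_dbs <- function(ref, alt) {
  n <- length(ref)
  stopifnot(length(alt) == n)
  if (any(nchar(ref) != 2L | nchar(alt) != 2L))
    stop("classify_dbs() expects doublet substitutions (DNV records)")
  shared <- substr(ref, 1, 1) == substr(alt, 1, 1) |
    substr(ref, 2, 2) == substr(alt, 2, 2)
  if (any(shared))
    stop("invalid DNV: ref and alt share a base at the same offset")
  map <- dbs78_map()
  lab <- map[paste0(ref, ">", alt)]
  if (anyNA(lab)) stop("DNV alleles must be A/C/G/T doublets")
  unname(lab)
}

# Full mapping of all 144 valid doublet substitutions onto the 78 channels by
# reverse-complement closure of the canonical table.
dbs78_map <- function() {
  cache <- getOption(".sigscape_dbs_map")
  if (!is.null(cache)) return(cache)
  labels <- dbs78_labels()
  map <- stats::setNames(labels, labels)
  doublets <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  for (ref in doublets) {
    for (alt in doublets) {
      if (substr(ref, 1, 1) == substr(alt, 1, 1)) next
      if (substr(ref, 2, 2) == substr(alt, 2, 2)) next
      key <- paste0(ref, ">", alt)
      if (!is.na(map[key])) next
      rc <- paste0(revcomp(ref), ">", revcomp(alt))
      map[key] <- map[rc]
    }
  }
  options(.sigscape_dbs_map = map)
  map
}

# run-length helpers for indel classification -------------------------------

prefix_run <- function(s, base) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  run <- 0L
  for (ch in chars) {
    if (ch != base) break
    run <- run + 1L
  }
  run
}

suffix_run <- function(s, base) {
  prefix_run(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), base)
}

prefix_copies <- function(s, unit) {
  l <- nchar(unit)
  copies <- 0L
  while (substr(s, copies * l + 1L, (copies + 1L) * l) == unit) {
    copies <- copies + 1L
  }
  copies
}

suffix_copies <- function(s, unit) {
  l <- nchar(unit)
  n <- nchar(s)
  copies <- 0L
  while ((copies + 1L) * l <= n &&
         substr(s, n - (copies + 1L) * l + 1L, n - copies * l) == unit) {
    copies <- copies + 1L
  }
  copies
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  k <- 0L
  while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  k
}

longest_common_suffix <- function(a, b) {
  rev1 <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  longest_common_prefix(rev1(a), rev1(b))
}

#' Classify insertions and deletions into ID83 channels
#'
#' Implements the COSMIC ID83 scheme. Single-base events are
#' complement-normalized to C/T and binned by homopolymer copy number
#' (deletions count copies including the deleted base, bins 1..6+ encoded
#' 0..5; insertions count pre-existing reference copies, bins 0..5+). Longer
#' events are binned by repeat copy number of the event unit (maximal tandem
#' copies around the locus) and by length 2, 3, 4, 5+. Deletions of two or
#' more bases with exactly one copy and flanking microhomology of at least one
#' base fall into the microhomology channels.
#'
#' @param ref Deleted sequence, or `"-"` for insertions.
#' @param alt Inserted sequence, or `"-"` for deletions.
#' @param context5 At least 10 bases immediately 5' of the event.
#' @param context3 At least `max(10, 5 * event length)` bases immediately 3'.
#' @return Character vector of ID83 channel labels.
#' @examples
#' classify_indel("T", "-", "GCAGTACGAC", "TTTTTAGGCAGTCA")  # "1:Del:T:5"
#' @export
classify_indel <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  vapply(seq_len(n), function(i) {
    classify_indel1(ref[i], alt[i], context5[i], context3[i])
  }, character(1))
}

classify_indel1 <- function(ref, alt, context5, context3) {
  is_del <- alt == "-"
  is_ins <- ref == "-"
  if (is_del == is_ins)
    stop("classify_indel() expects INS (ref = '-') or DEL (alt = '-') records")
  seqv <- if (is_del) ref else alt
  len <- nchar(seqv)
  if (len < 1L || grepl("[^ACGT]", seqv))
    stop("indel sequence must be non-empty over A/C/G/T")
  if (nchar(context5) < 10L || nchar(context3) < max(10L, 5L * len))
    stop("insufficient context for the ID83 scan window")
  if (grepl("[^ACGT]", context5) || grepl("[^ACGT]", context3))
    stop("context must contain only A/C/G/T")

  if (len == 1L) {
    run <- suffix_run(context5, seqv) + prefix_run(context3, seqv)
    pyr <- if (seqv %in% PYRIMIDINES) seqv else comp_base(seqv)
    if (is_del) {
      paste0("1:Del:", pyr, ":", min(run + 1L, 6L) - 1L)
    } else {
      paste0("1:Ins:", pyr, ":", min(run, 5L))
    }
  } else {
    len_lab <- min(len, 5L)
    copies <- prefix_copies(context3, seqv) + suffix_copies(context5, seqv)
    if (is_del) {
      copies <- copies + 1L
      if (copies == 1L) {
        hom <- max(longest_common_prefix(seqv, context3),
                   longest_common_suffix(seqv, context5))
        if (hom >= 1L) {
          return(paste0(len_lab, ":Del:M:", min(hom, 5L)))
        }
      }
      paste0(len_lab, ":Del:R:", min(copies, 6L) - 1L)
    } else {
      paste0(len_lab, ":Ins:R:", min(copies, 5L))
    }
  }
}

#' Classify a tibble of mutation records into channels
#'
#' Adds a `channel` column for the records matching the scheme's mutation
#' kind (SNV for SBS96, DNV for DBS78, INS/DEL for ID83); other records are
#' dropped.
#'
#' @param records Tibble of mutation records as returned by [read_ssm()] or
#'   [simulate_ssm_records()].
#' @param scheme Channel scheme.
#' @return The matching records with a `channel` column appended.
#' @export
classify_mutations <- function(records, scheme = c("SBS96", "DBS78", "ID83")) {
  scheme <- match.arg(scheme)
  kinds <- switch(scheme,
    SBS96 = "SNV",
    DBS78 = "DNV",
    ID83  = c("INS", "DEL")
  )
  rec <- dplyr::filter(records, .data$kind %in% kinds)
  if (nrow(rec) == 0L) {
    return(dplyr::mutate(rec, channel = character(0)))
  }
  rec$channel <- switch(scheme,
    SBS96 = classify_sbs(rec$ref, rec$alt, rec$context5, rec$context3),
    DBS78 = classify_dbs(rec$ref, rec$alt),
    ID83  = classify_indel(rec$ref, rec$alt, rec$context5, rec$context3)
  )
  rec
}
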
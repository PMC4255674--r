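# Tn-tag extraction from raw reads.
#
# Read anatomy (5' -> 3'): 53 bp of transposon sequence whose last 27 bp are
# the MmeI-adapted inverted repeat (IR), then 15-16 bp of genomic DNA flanking
# the insertion (the tag, which must begin with the TA the transposon sits in),
# then library adapter. Tags are recovered by quality trimming, locating the
# IR, and taking the following 15-16 bases.

# Default IR used when the caller does not supply the construct's own; the
# himar1 mariner inverted repeat with the MmeI-adapted terminus.
DEFAULT_IR <- "ACAGGTTGGATGATAAGTCCCCGGTCT"

#' Describe the expected read structure
#'
#' Bundles the constants the tag extractor and read simulator share: total
#' transposon prefix length (53 bp, ending in the 27 bp inverted repeat),
#' genomic tag length range (15-16 bp, set by MmeI cutting 20/18 nt from its
#' site), sequencing template length (187 bp) and the Phred quality floor
#' (Q20) used for 3' trimming.
#'
#' @param ir_sequence The inverted-repeat sequence terminating the transposon
#'   portion of each read.
#' @param transposon_len Total transposon prefix length in bases.
#' @param tag_len_min,tag_len_max Genomic tag length range in bases.
#' @param template_len Sequencing template length in bases.
#' @param quality_floor Phred floor for 3' quality trimming.
#' @return A list of class `read_structure`.
#' @export
read_structure <- function(ir_sequence = DEFAULT_IR,
                           transposon_len = 53L,
                           tag_len_min = 15L,
                           tag_len_max = 16L,
                           template_len = 187L,
                           quality_floor = 20L) {
  ir_sequence <- toupper(ir_sequence)
  stopifnot(
    grepl("^[ACGT]+$", ir_sequence),
    tag_len_min <= tag_len_max,
    transposon_len >= nchar(ir_sequence),
    quality_floor >= 0
  )
  structure(
    list(
      ir_sequence = ir_sequence,
      ir_len = nchar(ir_sequence),
      transposon_len = as.integer(transposon_len),
      tag_len_min = as.integer(tag_len_min),
      tag_len_max = as.integer(tag_len_max),
      template_len = as.integer(template_len),
      quality_floor = as.integer(quality_floor)
    ),
    class = "read_structure"
  )
}

#' 3' quality trimming
#'
#' Removes the 3' suffix maximizing the partial sum of `(floor - q)` (the
#' classic BWA-style trimming rule): scanning from the 3' end, the read is cut
#' at the position where the running sum of `(floor - quality)` is largest,
#' provided that maximum is positive. Reads that are low quality throughout
#' trim to the empty string. Ties favour the longer retained read.
#'
#' @param seq Character scalar, the read sequence.
#' @param quals Integer vector of Phred qualities, one per base.
#' @param floor Phred floor (default 20).
#' @return The trimmed sequence (possibly `""`).
#' @export
quality_trim <- function(seq, quals, floor = 20L) {
  n <- nchar(seq)
  if (length(quals) != n) {
    stop("quality vector length (", length(quals),
         ") does not match read length (", n, ")")
  }
  cut <- quality_trim_point(quals, floor)
  if (cut > n) seq else substr(seq, 1L, cut - 1L)
}

# First trimmed position (n + 1 means keep everything). Shared by the
# scalar and vectorized paths.
quality_trim_point <- function(quals, floor) {
  n <- length(quals)
  if (n == 0L) return(1L)
  s <- rev(cumsum(rev(floor - quals)))  # s[i] = sum_{j >= i}(floor - q_j)
  m <- max(s)
  if (m <= 0) return(n + 1L)
  max(which(s == m))  # latest maximizing cut keeps the most bases
}

#' Extract the genomic Tn-tag from one quality-trimmed read
#'
#' Locates the inverted repeat (exact match by default, or allowing one
#' mismatch), takes the following 15-16 bases as the genomic tag (16 when
#' available, else 15), and requires the tag to begin with `TA` -- the motif
#' the mariner transposon inserted into. Failures are returned as data, one of
#' `no_ir`, `bad_length`, `no_ta`.
#'
#' @param seq Quality-trimmed read sequence.
#' @param structure A [read_structure()].
#' @param ir_mismatches Mismatches tolerated when locating the IR (0 or 1).
#' @return A list with either `$tag` (and `$tag_start`) or `$reason`.
#' @export
extract_tag <- function(seq, structure = read_structure(), ir_mismatches = 0L) {
  ir_end <- locate_ir_end(seq, structure$ir_sequence, ir_mismatches)
  if (is.na(ir_end)) {
    return(list(tag = NA_character_, reason = "no_ir"))
  }
  rest_len <- nchar(seq) - ir_end
  if (rest_len < structure$tag_len_min) {
    return(list(tag = NA_character_, reason = "bad_length"))
  }
  k <- min(structure$tag_len_max, rest_len)
  tag <- substr(seq, ir_end + 1L, ir_end + k)
  if (substr(tag, 1L, 2L) != "TA") {
    return(list(tag = NA_character_, reason = "no_ta"))
  }
  list(tag = tag, reason = NA_character_, tag_start = ir_end + 1L)
}

# 1-based position of the last IR base, or NA if absent.
locate_ir_end <- function(seq, ir, mismatches = 0L) {
  if (mismatches == 0L) {
    p <- regexpr(ir, seq, fixed = TRUE)
    if (p < 0L) return(NA_integer_)
    return(as.integer(p) + nchar(ir) - 1L)
  }
  hits <- Biostrings::matchPattern(ir, Biostrings::DNAString(seq),
                                   max.mismatch = mismatches, fixed = TRUE)
  if (length(hits) == 0L) return(NA_integer_)
  Biostrings::end(hits)[1L]
}

#' Process a FASTQ file into validated Tn-tags
#'
#' Streams every read through [quality_trim()] then [extract_tag()] and
#' reports attrition. A trimmed read too short to contain the inverted repeat
#' plus a minimum-length tag is counted as `quality_fail`; the remaining
#' categories come from [extract_tag()]. Every input read lands in exactly one
#' category, so the stats conserve the read count.
#'
#' @param fastq_path Path to a FASTQ file (Sanger Phred+33), possibly empty.
#' @param structure A [read_structure()].
#' @param ir_mismatches Mismatches tolerated when locating the IR.
#' @return List with `$tags` (data.frame `read_id`, `tag`, `source_read_len`)
#'   and `$stats` (class `processing_stats`).
#' @export
process_fastq <- function(fastq_path, structure = read_structure(),
                          ir_mismatches = 0L) {
  if (!file.exists(fastq_path)) {
    stop("FASTQ not found: ", fastq_path)
  }
  empty <- function() {
    list(
      tags = data.frame(read_id = character(), tag = character(),
                        source_read_len = integer(),
                        stringsAsFactors = FALSE),
      stats = processing_stats(0L, 0L, 0L, 0L, 0L, 0L)
    )
  }
  if (file.size(fastq_path) == 0L) return(empty())
  reads <- Biostrings::readDNAStringSet(fastq_path, format = "fastq",
                                        with.qualities = TRUE)
  n <- length(reads)
  if (n == 0L) return(empty())
  ids <- sub("\\s.*$", "", names(reads))
  seqs <- as.character(reads)
  qlist <- as(Biostrings::PhredQuality(S4Vectors::mcols(reads)$qualities),
              "IntegerList")
  floor <- structure$quality_floor
  trimmed <- character(n)
  for (i in seq_len(n)) {
    q <- qlist[[i]]
    cut <- quality_trim_point(q, floor)
    trimmed[i] <- if (cut > length(q)) seqs[i] else substr(seqs[i], 1L, cut - 1L)
  }
  min_len <- structure$ir_len + structure$tag_len_min
  category <- character(n)
  tag <- rep(NA_character_, n)

  qfail <- nchar(trimmed) < min_len
  category[qfail] <- "quality_fail"

  todo <- which(!qfail)
  if (ir_mismatches == 0L) {
    ir_pos <- regexpr(structure$ir_sequence, trimmed[todo], fixed = TRUE)
    ir_end <- ifelse(ir_pos > 0L, as.integer(ir_pos) + structure$ir_len - 1L,
                     NA_integer_)
  } else {
    ir_end <- vapply(trimmed[todo], locate_ir_end, integer(1),
                     ir = structure$ir_sequence, mismatches = ir_mismatches,
                     USE.NAMES = FALSE)
  }
  no_ir <- is.na(ir_end)
  category[todo[no_ir]] <- "no_ir"

  hit <- todo[!no_ir]
  hit_end <- ir_end[!no_ir]
  rest_len <- nchar(trimmed[hit]) - hit_end
  short <- rest_len < structure$tag_len_min
  category[hit[short]] <- "bad_length"

  ok <- hit[!short]
  ok_end <- hit_end[!short]
  k <- pmin(structure$tag_len_max, rest_len[!short])
  cand <- substr(trimmed[ok], ok_end + 1L, ok_end + k)
  has_ta <- substr(cand, 1L, 2L) == "TA"
  category[ok[!has_ta]] <- "no_ta"
  category[ok[has_ta]] <- "tag"
  tag[ok[has_ta]] <- cand[has_ta]

  keep <- category == "tag"
  list(
    tags = data.frame(read_id = ids[keep], tag = tag[keep],
                      source_read_len = nchar(seqs)[keep],
                      stringsAsFactors = FALSE),
    stats = processing_stats(
      n_input = n,
      n_quality_fail = sum(category == "quality_fail"),
      n_no_ir = sum(category == "no_ir"),
      n_bad_length = sum(category == "bad_length"),
      n_no_ta = sum(category == "no_ta"),
      n_tags = sum(keep)
    )
  )
}

processing_stats <- function(n_input, n_quality_fail, n_no_ir, n_bad_length,
                             n_no_ta, n_tags) {
  s <- list(n_input = n_input, n_quality_fail = n_quality_fail,
            n_no_ir = n_no_ir, n_bad_length = n_bad_length,
            n_no_ta = n_no_ta, n_tags = n_tags)
  stopifnot(n_input == n_quality_fail + n_no_ir + n_bad_length + n_no_ta + n_tags)
  class(s) <- "processing_stats"
  s
}

#' @export
print.processing_stats <- function(x, ...) {
  cat(sprintf(
    "reads in: %d | quality fail: %d | no IR: %d | bad length: %d | no TA: %d | tags out: %d\n",
    x$n_input, x$n_quality_fail, x$n_no_ir, x$n_bad_length, x$n_no_ta, x$n_tags))
  invisible(x)
}

#' Write extracted tags as a two-column TSV
#' @param tags data.frame from [process_fastq()] (`$tags`).
#' @param path Output path.
#' @export
write_tags_tsv <- function(tags, path) {
  data.table::fwrite(tags[, c("read_id", "tag")], path, sep = "\t")
  invisible(path)
}

#' Read a tag TSV written by [write_tags_tsv()]
#' @param path Input path.
#' @return data.frame with `read_id` and `tag` columns.
#' @export
read_tags_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", colClasses = "character"))
}
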
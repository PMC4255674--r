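# Exact unique mapping of 15-16 bp Tn-tags to TA sites.
#
# Every genomic substring of length 15 and 16 that begins at a TA site -- on
# either strand, reading away from the TA -- is indexed in a hash table. A tag
# maps if and only if it is exactly equal to an indexed context occurring at a
# single site (zero mismatches, unique placement); tags matching more than one
# site are discarded as multi-mappers. This replaces a general-purpose aligner:
# for fixed-length exact lookups a k-mer table is both faster and strictly
# more predictable.

#' Build the TA-anchored k-mer index of a genome
#'
#' For each TA site at position `p` the forward contexts `seq[p..p+14]` and
#' `seq[p..p+15]` and the reverse-strand contexts (reverse complement of the
#' windows ending at `p+1`, so they too begin with `TA`) are recorded. Sites
#' too close to a replicon end are indexed only for the lengths that fit. A
#' k-mer seen at more than one distinct site is flagged ambiguous.
#'
#' @param genome `DNAStringSet` from [load_genome()].
#' @param ta TA index from [ta_site_index()].
#' @return An object of class `tag_index`.
#' @export
build_tag_index <- function(genome, ta) {
  stopifnot(identical(names(genome), names(ta)))
  pieces <- vector("list", 4L * length(genome))
  j <- 0L
  for (r in names(genome)) {
    chr <- as.character(genome[[r]])
    len <- nchar(chr)
    p <- ta[[r]]
    for (k in c(15L, 16L)) {
      fwd_ok <- p + k - 1L <= len
      if (any(fwd_ok)) {
        pf <- p[fwd_ok]
        j <- j + 1L
        pieces[[j]] <- data.table::data.table(
          kmer = substring(chr, pf, pf + k - 1L),
          replicon_id = r, position = pf, strand = "+")
      }
      rev_ok <- p - k + 2L >= 1L
      if (any(rev_ok)) {
        pr <- p[rev_ok]
        ctx <- substring(chr, pr - k + 2L, pr + 1L)
        rc <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx)))
        j <- j + 1L
        pieces[[j]] <- data.table::data.table(
          kmer = rc, replicon_id = r, position = pr, strand = "-")
      }
    }
  }
  dt <- data.table::rbindlist(pieces[seq_len(j)])
  # Drop N-containing contexts: unmappable under the exact-match contract.
  dt <- dt[!grepl("N", dt$kmer, fixed = TRUE)]
  # A palindromic context can index the same site from both strands; that is
  # still a unique site, so deduplicate on (kmer, site) before flagging.
  dt <- unique(dt, by = c("kmer", "replicon_id", "position"))
  kmer <- NULL  # appease R CMD check; data.table NSE
  lookup <- dt[, list(replicon_id = replicon_id[1L],
                      position = position[1L],
                      strand = strand[1L],
                      n_sites = .N), by = kmer]
  data.table::setkeyv(lookup, "kmer")
  structure(list(lookup = lookup, replicon_ids = names(genome)),
            class = "tag_index")
}

#' Map a vector of tags against the index
#'
#' Exact lookup of each tag; a 16-mer with no entry is retried as its 15-mer
#' prefix (MmeI leaves the tag length ambiguous between 15 and 16, so the
#' extractor emits 16 when it can and the mapper falls back). Lookups hitting
#' more than one site return `multi`; everything else `unmapped`.
#'
#' @param tags Character vector of tags (each starting `TA`, length 15 or 16).
#' @param index A [build_tag_index()] result.
#' @return data.frame with columns `tag`, `status` (`unique`/`multi`/
#'   `unmapped`), `replicon_id`, `position`, `strand`.
#' @export
map_tags <- function(tags, index) {
  if (length(tags) && any(substr(tags, 1L, 2L) != "TA")) {
    stop("tags must start with 'TA' (contract violation)")
  }
  lk <- index$lookup
  hit <- lk[data.table::data.table(kmer = tags), on = "kmer"]
  retry <- which(is.na(hit$n_sites) & nchar(tags) == 16L)
  if (length(retry)) {
    hit15 <- lk[data.table::data.table(kmer = substr(tags[retry], 1L, 15L)),
                on = "kmer"]
    hit$replicon_id[retry] <- hit15$replicon_id
    hit$position[retry] <- hit15$position
    hit$strand[retry] <- hit15$strand
    hit$n_sites[retry] <- hit15$n_sites
  }
  status <- ifelse(is.na(hit$n_sites), "unmapped",
                   ifelse(hit$n_sites > 1L, "multi", "unique"))
  uniq <- status == "unique"
  data.frame(
    tag = tags,
    status = status,
    replicon_id = ifelse(uniq, hit$replicon_id, NA_character_),
    position = ifelse(uniq, hit$position, NA_integer_),
    strand = ifelse(uniq, hit$strand, NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Map a single tag
#'
#' @param tag One tag string.
#' @param index A [build_tag_index()] result.
#' @return List with `status` and, for unique hits, `replicon_id`, `position`,
#'   `strand`.
#' @export
map_tag <- function(tag, index) {
  res <- map_tags(tag, index)
  if (res$status[1L] != "unique") return(list(status = res$status[1L]))
  list(status = "unique", replicon_id = res$replicon_id[1L],
       position = res$position[1L], strand = res$strand[1L])
}

#' Accumulate mapped tags into per-replicon insertion profiles
#'
#' Counts unique-mapping tags per TA site, pooling both strands (the TA motif
#' is its own reverse complement, and the saturation statistics are site-level
#' and strand-free). Duplicate reads are deliberately not collapsed: the
#' profile holds read counts.
#'
#' @param hits data.frame from [map_tags()].
#' @param ta TA index from [ta_site_index()].
#' @return List with `$profiles` (named list of integer count vectors aligned
#'   to `ta`) and `$stats` (class `mapping_stats`).
#' @export
accumulate_profile <- function(hits, ta) {
  profiles <- lapply(ta, function(p) integer(length(p)))
  uniq <- hits[hits$status == "unique", , drop = FALSE]
  for (r in names(ta)) {
    h <- uniq[uniq$replicon_id == r, , drop = FALSE]
    if (nrow(h) == 0L) next
    idx <- match(h$position, ta[[r]])
    if (anyNA(idx)) stop("mapped position not in TA index for ", r)
    profiles[[r]] <- profiles[[r]] + tabulate(idx, nbins = length(ta[[r]]))
  }
  stats <- mapping_stats(
    n_tags = nrow(hits),
    n_unique = sum(hits$status == "unique"),
    n_multi = sum(hits$status == "multi"),
    n_unmapped = sum(hits$status == "unmapped")
  )
  list(profiles = profiles, stats = stats)
}

mapping_stats <- function(n_tags, n_unique, n_multi, n_unmapped) {
  stopifnot(n_tags == n_unique + n_multi + n_unmapped)
  structure(list(n_tags = n_tags, n_unique = n_unique, n_multi = n_multi,
                 n_unmapped = n_unmapped),
            class = "mapping_stats")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat(sprintf("tags: %d | unique: %d | multi: %d | unmapped: %d\n",
              x$n_tags, x$n_unique, x$n_multi, x$n_unmapped))
  invisible(x)
}
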
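#' Load a multi-replicon genome from FASTA
#'
#' Reads every record of a (multi-)FASTA file into a [Biostrings::DNAStringSet],
#' one element per replicon, in file order. Sequences are stored in the
#' uppercase DNA alphabet; IUPAC ambiguity codes are tolerated, anything else
#' is a format error. Record names are truncated at the first whitespace, so
#' `>chr some description` becomes replicon id `chr`.
#'
#' @param fasta_path Path to a FASTA file with at least one record.
#' @return A named `DNAStringSet`, one entry per replicon.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path)
  }
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(fasta_path, format = "fasta"),
      error = function(e) stop("invalid FASTA '", fasta_path, "': ",
                               conditionMessage(e), call. = FALSE)
    ),
    warning = function(w) {
      # the reader silently drops letters outside the IUPAC alphabet; treat
      # that as a format error rather than analyse a truncated sequence
      if (grepl("invalid one-letter sequence code", conditionMessage(w))) {
        stop("invalid FASTA '", fasta_path, "': non-IUPAC sequence characters",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L) {
    stop("no sequence records in FASTA: ", fasta_path)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate replicon ids in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs
}

#' Per-replicon length and GC content
#'
#' GC fraction is computed over unambiguous bases only (G+C over A+C+G+T), so
#' runs of N do not dilute it.
#'
#' @param genome A `DNAStringSet` as returned by [load_genome()].
#' @return A data.frame with columns `replicon_id`, `length`, `gc_fraction`.
#' @export
replicon_info <- function(genome) {
  gc <- Biostrings::letterFrequency(genome, letters = c("G", "C"))
  acgt <- Biostrings::letterFrequency(genome, letters = c("A", "C", "G", "T"))
  denom <- rowSums(acgt)
  data.frame(
    replicon_id = names(genome),
    length = Biostrings::width(genome),
    gc_fraction = ifelse(denom > 0, rowSums(gc) / denom, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Enumerate mariner insertion sites (TA dinucleotides) in one sequence
#'
#' Every 1-based position `p` with `seq[p] == "T"` and `seq[p+1] == "A"` is a
#' potential mariner insertion site; the site coordinate is the position of the
#' T. Occurrences in consecutive TATA runs are all reported, and positions
#' involving ambiguity codes (e.g. `TN`) are not sites.
#'
#' @param sequence A `DNAString`, or a character scalar.
#' @return Sorted integer vector of site positions (possibly empty).
#' @export
enumerate_ta_sites <- function(sequence) {
  if (is.character(sequence)) {
    sequence <- Biostrings::DNAString(sequence)
  }
  if (length(sequence) == 0L) {
    stop("empty sequence")
  }
  Biostrings::start(Biostrings::matchPattern("TA", sequence, fixed = TRUE))
}

#' TA site index for a whole genome
#'
#' @param genome A `DNAStringSet`.
#' @return Named list of integer vectors (one per replicon, in genome order),
#'   with attribute `replicon_lengths`.
#' @export
ta_site_index <- function(genome) {
  idx <- lapply(seq_along(genome), function(i) enumerate_ta_sites(genome[[i]]))
  names(idx) <- names(genome)
  attr(idx, "replicon_lengths") <- stats::setNames(Biostrings::width(genome),
                                                   names(genome))
  idx
}

#' Load gene annotations from GFF3
#'
#' Imports a GFF3 file and keeps features of the requested type. Each feature
#' must carry an `ID` or `locus_tag` attribute, which becomes the locus name.
#' Features on replicons absent from `replicon_lengths` are dropped with a
#' warning; features whose coordinates exceed the replicon length are an error.
#'
#' @param gff_path Path to a GFF3 file.
#' @param replicon_lengths Named integer vector of replicon lengths (e.g.
#'   from [replicon_info()]), used for validation.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return data.frame with columns `locus`, `replicon_id`, `start`, `end`,
#'   `strand`, `product`.
#' @export
load_annotation <- function(gff_path, replicon_lengths, feature_type = "gene") {
  if (!file.exists(gff_path)) {
    stop("annotation GFF3 not found: ", gff_path)
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  if (length(gr) == 0L) {
    return(data.frame(locus = character(), replicon_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      product = character(), stringsAsFactors = FALSE))
  }
  meta <- S4Vectors::mcols(gr)
  locus <- if ("locus_tag" %in% names(meta) && !all(is.na(meta$locus_tag))) {
    as.character(meta$locus_tag)
  } else {
    NULL
  }
  if (is.null(locus) && "ID" %in% names(meta)) {
    locus <- as.character(meta$ID)
  }
  if (is.null(locus) || anyNA(locus)) {
    stop("GFF3 features of type '", feature_type,
         "' must carry an ID or locus_tag attribute")
  }
  product <- if ("product" %in% names(meta)) {
    as.character(meta$product)
  } else if ("Name" %in% names(meta)) {
    as.character(meta$Name)
  } else {
    rep(NA_character_, length(gr))
  }
  ann <- data.frame(
    locus = locus,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = product,
    stringsAsFactors = FALSE
  )
  known <- ann$replicon_id %in% names(replicon_lengths)
  if (any(!known)) {
    warning("dropping ", sum(!known), " feature(s) on unknown replicon(s): ",
            paste(unique(ann$replicon_id[!known]), collapse = ", "))
    ann <- ann[known, , drop = FALSE]
  }
  too_far <- ann$end > replicon_lengths[ann$replicon_id] | ann$start < 1L
  if (any(too_far)) {
    stop("feature(s) outside replicon bounds: ",
         paste(ann$locus[too_far], collapse = ", "))
  }
  rownames(ann) <- NULL
  ann
}

#' Map genes to the TA sites they contain
#'
#' A TA site belongs to a gene iff both of its bases lie inside the gene, i.e.
#' `start <= p` and `p + 1 <= end`. A site whose T sits exactly on the gene's
#' last base therefore does not count. Genes with no sites map to an empty
#' vector; these are the "No Data" genes downstream.
#'
#' @param positions Sorted integer vector of TA site positions on one replicon.
#' @param genes Annotation data.frame (rows for this replicon) with `start`,
#'   `end`, `locus` columns.
#' @return Named list, one sorted integer vector of indices into `positions`
#'   per gene locus.
#' @export
sites_per_gene <- function(positions, genes) {
  out <- vector("list", nrow(genes))
  names(out) <- genes$locus
  if (nrow(genes) == 0L) return(out)
  for (i in seq_len(nrow(genes))) {
    lo <- genes$start[i]
    hi <- genes$end[i] - 1L  # site p needs p + 1 <= end
    if (hi < lo) {
      out[[i]] <- integer()
      next
    }
    first <- findInterval(lo - 1L, positions) + 1L
    last <- findInterval(hi, positions)
    out[[i]] <- if (first > last) integer() else seq.int(first, last)
  }
  out
}

#' Gene-site maps for a whole genome
#'
#' @param ta Index from [ta_site_index()].
#' @param annotation Full annotation data.frame from [load_annotation()].
#' @return Named list (by replicon) of [sites_per_gene()] results.
#' @export
gene_site_maps <- function(ta, annotation) {
  out <- lapply(names(ta), function(r) {
    sites_per_gene(ta[[r]], annotation[annotation$replicon_id == r, ,
                                       drop = FALSE])
  })
  names(out) <- names(ta)
  out
}

#' Write a TA site index as BED
#'
#' One 2 bp interval per site, 0-based half-open as BED requires.
#'
#' @param ta Index from [ta_site_index()].
#' @param path Output path.
#' @export
write_ta_bed <- function(ta, path) {
  rows <- lapply(names(ta), function(r) {
    p <- ta[[r]]
    if (length(p) == 0L) return(NULL)
    data.frame(chrom = r, start = p - 1L, end = p + 1L)
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a TA site index as TSV (replicon, 1-based position)
#'
#' @param ta Index from [ta_site_index()].
#' @param path Output path.
#' @export
write_ta_tsv <- function(ta, path) {
  rows <- lapply(names(ta), function(r) {
    p <- ta[[r]]
    if (length(p) == 0L) return(NULL)
    data.frame(replicon_id = r, position = p)
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
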
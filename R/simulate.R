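# Synthetic INSeq experiment generator: genome, annotation with ground-truth
# fitness classes, per-site insertion profiles, and raw reads. Defaults mirror
# a near-saturating mariner mutagenesis of a multi-replicon alpha-proteobacterial
# genome: ~0.83 site occupancy, ~19.4 reads per occupied site, class mix
# ES 5.6% / GD 4.0% / GA 0.5% / NE the rest, and one small replicon at
# elevated copy number (higher read depth, same density).

#' Simulation configuration
#'
#' @param seed Integer master seed; all randomness derives from it, and
#'   per-replicon substreams are decorrelated so adding a replicon does not
#'   perturb earlier ones.
#' @param replicon_lengths Integer vector of replicon sizes in bp.
#' @param gc_fractions GC content per replicon (recycled).
#' @param gene_density Genes per kb.
#' @param class_proportions Named probabilities for `ES`, `GD`, `NE`, `GA`
#'   (must sum to 1).
#' @param target_occupancy Probability that a neutral TA site carries at least
#'   one insertion.
#' @param mean_reads_per_site Mean read count at an occupied neutral site.
#' @param copy_number_factors Per-replicon read-depth multipliers (recycled);
#'   values above 1 emulate higher plasmid copy number.
#' @param read_error_rate Per-base substitution probability in simulated reads.
#' @param es_edge_permissive If `TRUE`, the terminal 10% of each essential
#'   gene's sites may carry low-count insertions, stress-testing the run-based
#'   classifier; default `FALSE` (essential genes are fully devoid of reads).
#' @param replicon_ids Optional replicon labels (default `sim01`, `sim02`...).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       replicon_lengths = c(450000L, 80000L),
                       gc_fractions = c(0.61, 0.58),
                       gene_density = 0.95,
                       class_proportions = c(ES = 0.056, GD = 0.040,
                                             NE = 0.899, GA = 0.005),
                       target_occupancy = 0.83,
                       mean_reads_per_site = 19.4,
                       copy_number_factors = c(1, 1.14),
                       read_error_rate = 0.005,
                       es_edge_permissive = FALSE,
                       replicon_ids = NULL) {
  k <- length(replicon_lengths)
  gc_fractions <- rep_len(gc_fractions, k)
  copy_number_factors <- rep_len(copy_number_factors, k)
  if (is.null(replicon_ids)) replicon_ids <- sprintf("sim%02d", seq_len(k))
  class_proportions <- class_proportions[HMM_STATES]
  stopifnot(
    abs(sum(class_proportions) - 1) < 1e-8,
    all(class_proportions >= 0),
    target_occupancy > 0, target_occupancy <= 1,
    mean_reads_per_site > 1,
    gene_density > 0,
    read_error_rate >= 0, read_error_rate < 1,
    length(replicon_ids) == k
  )
  structure(
    list(seed = as.integer(seed), replicon_lengths = as.integer(replicon_lengths),
         gc_fractions = gc_fractions, gene_density = gene_density,
         class_proportions = class_proportions,
         target_occupancy = target_occupancy,
         mean_reads_per_site = mean_reads_per_site,
         copy_number_factors = copy_number_factors,
         read_error_rate = read_error_rate,
         es_edge_permissive = es_edge_permissive,
         replicon_ids = replicon_ids),
    class = "sim_config"
  )
}

# Deterministic per-(replicon, stage) substream seed, kept within 32-bit range.
substream_seed <- function(seed, replicon, stage) {
  as.integer((as.double(seed) * 48271 + replicon * 100003 + stage * 7919) %%
               2147483647)
}

#' Simulate a multi-replicon genome with annotated genes
#'
#' Bases are i.i.d. at the configured GC. Genes are tiled non-overlapping at
#' the configured density (regular spacing, genes covering ~80% of each tile),
#' alternating strand, and each is assigned a true fitness class drawn from
#' `class_proportions`.
#'
#' @param config A [sim_config()].
#' @return List of class `inseq_sim` with `$genome` (`DNAStringSet`),
#'   `$genes` (annotation data.frame with a `true_class` column), `$config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- vector("list", length(config$replicon_lengths))
  gene_rows <- list()
  spacing <- max(200L, as.integer(round(1000 / config$gene_density)))
  gene_len <- as.integer(round(0.8 * spacing))
  for (k in seq_along(config$replicon_lengths)) {
    len <- config$replicon_lengths[k]
    gc <- config$gc_fractions[k]
    set.seed(substream_seed(config$seed, k, 1L))
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    seqs[[k]] <- paste(bases, collapse = "")
    if (len < spacing + 100L) {
      stop("replicon of ", len, " bp cannot hold genes at density ",
           config$gene_density, " per kb")
    }
    starts <- seq.int(51L, len - gene_len - 50L, by = spacing)
    n_genes <- length(starts)
    classes <- sample(HMM_STATES, n_genes, replace = TRUE,
                      prob = config$class_proportions)
    gene_rows[[k]] <- data.frame(
      locus = sprintf("%s_%05d", config$replicon_ids[k], seq_len(n_genes)),
      replicon_id = config$replicon_ids[k],
      start = starts,
      end = starts + gene_len - 1L,
      strand = rep_len(c("+", "-"), n_genes),
      product = paste("hypothetical protein", seq_len(n_genes)),
      true_class = classes,
      stringsAsFactors = FALSE
    )
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- config$replicon_ids
  structure(list(genome = genome,
                 genes = do.call(rbind, gene_rows),
                 config = config),
            class = "inseq_sim")
}

#' Simulate per-site insertion counts given the true gene classes
#'
#' Occupancy is Bernoulli per TA site with a class-specific probability
#' (ES: 0; GD: 0.4 x target; NE and GA: target), and occupied sites draw a
#' shifted-geometric read count (minimum 1) with class-specific mean (GD:
#' 0.1x, NE: 1x, GA: 5x the configured mean), scaled by the replicon's copy
#' number factor. Intergenic sites behave as neutral, which is what makes the
#' context flanking a gene informative for the decoder.
#'
#' @param sim An `inseq_sim` from [simulate_genome()].
#' @return The `inseq_sim` augmented with `$ta` (TA index), `$profiles`
#'   (named list of per-site counts) and `$site_class` (named list of true
#'   per-site classes).
#' @export
simulate_counts <- function(sim) {
  stopifnot(inherits(sim, "inseq_sim"))
  config <- sim$config
  ta <- ta_site_index(sim$genome)
  profiles <- list()
  site_class <- list()
  occ_mult <- c(ES = 0, GD = 0.4, NE = 1, GA = 1)
  mean_mult <- c(ES = 0, GD = 0.1, NE = 1, GA = 5)
  for (k in seq_along(config$replicon_ids)) {
    r <- config$replicon_ids[k]
    pos <- ta[[r]]
    n <- length(pos)
    cls <- rep("NE", n)
    genes_r <- sim$genes[sim$genes$replicon_id == r, , drop = FALSE]
    smap <- sites_per_gene(pos, genes_r)
    edge_sites <- integer(0)
    for (i in seq_len(nrow(genes_r))) {
      idx <- smap[[i]]
      if (!length(idx)) next
      cls[idx] <- genes_r$true_class[i]
      if (config$es_edge_permissive && genes_r$true_class[i] == "ES") {
        n_edge <- floor(0.1 * length(idx))
        if (n_edge > 0L) {
          edge_sites <- c(edge_sites, utils::tail(idx, n_edge))
        }
      }
    }
    set.seed(substream_seed(config$seed, k, 2L))
    p_occ <- occ_mult[cls] * config$target_occupancy
    mu <- mean_mult[cls] * config$mean_reads_per_site *
      config$copy_number_factors[k]
    if (length(edge_sites)) {
      # Leaky essential termini: occasional low-count insertions.
      p_occ[edge_sites] <- 0.3 * config$target_occupancy
      mu[edge_sites] <- 1.5 * config$copy_number_factors[k]
    }
    occupied <- stats::runif(n) < p_occ
    counts <- integer(n)
    if (any(occupied)) {
      m_occ <- pmax(mu[occupied], 1.0001)
      counts[occupied] <- 1L + stats::rgeom(sum(occupied), prob = 1 / m_occ)
    }
    profiles[[r]] <- counts
    site_class[[r]] <- cls
  }
  sim$ta <- ta
  sim$profiles <- profiles
  sim$site_class <- site_class
  sim
}

# Fixed transposon prefix (26 bp filler + 27 bp IR = the 53 bp transposon
# portion of each read) and a trailing library adapter for padding.
SIM_ADAPTER <- "CTGAGTCGGAGACACGCAGGGATGAG"

sim_transposon_prefix <- function(structure) {
  filler_len <- structure$transposon_len - structure$ir_len
  filler <- strrep("GCTAGCTTGGCGCGCCTACGTAGCGA", ceiling(filler_len / 26))
  paste0(substr(filler, 1L, filler_len), structure$ir_sequence)
}

#' Simulate raw reads from insertion profiles
#'
#' Each site with count `c` emits `c` reads: the 53 bp transposon prefix
#' ending in the inverted repeat, then the 16 bp genomic context of the TA
#' read from a uniformly chosen strand (forward: the TA and the 14 bases
#' after it; reverse: the reverse complement of the TA and the 14 bases
#' before it -- both begin `TA`), then adapter padding. Per-base substitution
#' errors are applied at the configured rate and qualities are constant Q37.
#' Sites too close to a replicon edge for one orientation use the other; a
#' site too close on both sides is skipped with a warning.
#'
#' @param sim An `inseq_sim` from [simulate_counts()].
#' @param fastq_path Output FASTQ path.
#' @param structure A [read_structure()] shared with the tag extractor.
#' @param error_rate Per-base substitution probability; defaults to the
#'   config's `read_error_rate`.
#' @return Invisibly, the number of reads written.
#' @export
simulate_reads <- function(sim, fastq_path, structure = read_structure(),
                           error_rate = sim$config$read_error_rate) {
  stopifnot(inherits(sim, "inseq_sim"), !is.null(sim$profiles))
  config <- sim$config
  prefix <- sim_transposon_prefix(structure)
  all_seqs <- list()
  for (k in seq_along(config$replicon_ids)) {
    r <- config$replicon_ids[k]
    chr <- as.character(sim$genome[[r]])
    len <- nchar(chr)
    pos <- sim$ta[[r]]
    counts <- sim$profiles[[r]]
    occupied <- which(counts > 0L)
    if (!length(occupied)) next
    p_all <- rep.int(pos[occupied], counts[occupied])
    set.seed(substream_seed(config$seed, k, 3L))
    fwd_ok <- p_all + 15L <= len
    rev_ok <- p_all - 14L >= 1L
    lost <- !fwd_ok & !rev_ok
    if (any(lost)) {
      warning(sum(lost), " read(s) skipped at replicon-edge sites on ", r)
      p_all <- p_all[!lost]
      fwd_ok <- fwd_ok[!lost]
      rev_ok <- rev_ok[!lost]
    }
    use_fwd <- ifelse(fwd_ok & rev_ok, stats::runif(length(p_all)) < 0.5,
                      fwd_ok)
    tags <- character(length(p_all))
    if (any(use_fwd)) {
      pf <- p_all[use_fwd]
      tags[use_fwd] <- substring(chr, pf, pf + 15L)
    }
    if (any(!use_fwd)) {
      pr <- p_all[!use_fwd]
      ctx <- substring(chr, pr - 14L, pr + 1L)
      tags[!use_fwd] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx)))
    }
    all_seqs[[r]] <- paste0(prefix, tags, SIM_ADAPTER)
  }
  seqs <- unlist(all_seqs, use.names = FALSE)
  n_reads <- length(seqs)
  if (n_reads > 0L && error_rate > 0) {
    set.seed(substream_seed(config$seed, 0L, 4L))
    read_len <- nchar(seqs[1L])
    n_err <- stats::rbinom(n_reads, read_len, error_rate)
    for (i in which(n_err > 0L)) {
      at <- sample.int(read_len, n_err[i])
      for (p in at) {
        orig <- substr(seqs[i], p, p)
        sub <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
        substr(seqs[i], p, p) <- sub
      }
    }
  }
  con <- file(fastq_path, open = "wt")
  on.exit(close(con))
  if (n_reads > 0L) {
    qual <- strrep("F", nchar(seqs[1L]))  # Phred+33 'F' = Q37
    out <- character(4L * n_reads)
    out[seq(1L, by = 4L, length.out = n_reads)] <-
      sprintf("@r%07d", seq_len(n_reads))
    out[seq(2L, by = 4L, length.out = n_reads)] <- seqs
    out[seq(3L, by = 4L, length.out = n_reads)] <- "+"
    out[seq(4L, by = 4L, length.out = n_reads)] <- qual
    writeLines(out, con)
  }
  invisible(n_reads)
}

#' Write the simulated genome and annotation to FASTA + GFF3
#'
#' @param sim An `inseq_sim`.
#' @param fasta_path,gff_path Output paths.
#' @export
write_sim_genome <- function(sim, fasta_path, gff_path) {
  Biostrings::writeXStringSet(sim$genome, fasta_path)
  g <- sim$genes
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tinseqr_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s;product=%s",
            g$replicon_id, g$start, g$end, g$strand, g$locus, g$locus,
            gsub("[;=\t]", " ", g$product))
  )
  writeLines(lines, gff_path)
  invisible(gff_path)
}

#' Write the simulation ground truth as TSV
#'
#' One row per gene: locus, replicon, coordinates, strand and the true
#' fitness class used to generate the data.
#'
#' @param sim An `inseq_sim`.
#' @param path Output path.
#' @export
write_sim_truth <- function(sim, path) {
  data.table::fwrite(sim$genes, path, sep = "\t")
  invisible(path)
}

#' Echo a simulation config as a flat key=value file
#'
#' The file round-trips through [read_sim_config()] for exact re-runs.
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @export
write_sim_config <- function(config, path) {
  kv <- vapply(names(config), function(nm) {
    paste0(nm, "=", paste(config[[nm]], collapse = ","))
  }, character(1))
  writeLines(kv, path)
  invisible(path)
}

#' Read a simulation config written by [write_sim_config()]
#'
#' @param path Input path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) strsplit(x[2], ",")[[1]]),
                          vapply(kv, `[`, character(1), 1L))
  num <- function(x) as.numeric(x)
  cp <- num(vals$class_proportions)
  names(cp) <- HMM_STATES
  sim_config(
    seed = as.integer(vals$seed),
    replicon_lengths = as.integer(vals$replicon_lengths),
    gc_fractions = num(vals$gc_fractions),
    gene_density = num(vals$gene_density),
    class_proportions = cp,
    target_occupancy = num(vals$target_occupancy),
    mean_reads_per_site = num(vals$mean_reads_per_site),
    copy_number_factors = num(vals$copy_number_factors),
    read_error_rate = num(vals$read_error_rate),
    es_edge_permissive = as.logical(vals$es_edge_permissive),
    replicon_ids = vals$replicon_ids
  )
}
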
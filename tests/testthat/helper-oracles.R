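# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (sliding windows, exhaustive enumeration, dynamic programming) and
# share no code with the implementation they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), path)
  path
}

write_fastq <- function(seqs, quals = NULL, path = tempfile(fileext = ".fastq")) {
  if (is.null(quals)) quals <- vapply(seqs, function(s) strrep("I", nchar(s)), "")
  lines <- character(4L * length(seqs))
  if (length(seqs)) {
    lines[seq(1, by = 4, length.out = length(seqs))] <-
      sprintf("@read%04d", seq_along(seqs))
    lines[seq(2, by = 4, length.out = length(seqs))] <- seqs
    lines[seq(3, by = 4, length.out = length(seqs))] <- "+"
    lines[seq(4, by = 4, length.out = length(seqs))] <- quals
  }
  writeLines(lines, path)
  path
}

write_gff3 <- function(df, path = tempfile(fileext = ".gff3")) {
  type <- if ("type" %in% names(df)) df$type else "gene"
  writeLines(c(
    "##gff-version 3",
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
            df$replicon_id, type, df$start, df$end,
            if ("strand" %in% names(df)) df$strand else "+",
            df$locus, df$locus)
  ), path)
  path
}

# Sliding-window TA-site oracle: inspect every adjacent base pair directly.
ta_oracle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 2) return(integer())
  which(chars[-n] == "T" & chars[-1] == "A")
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# Exhaustive maximum-probability path oracle for tiny HMM instances:
# enumerate all 4^n paths and score them in log space.
viterbi_oracle <- function(counts, params) {
  n <- length(counts)
  stopifnot(n <= 8)
  emis <- sapply(params$emission_probs,
                 function(p) dgeom(counts, prob = p, log = TRUE))
  emis <- matrix(emis, nrow = n)
  ltr <- log(params$transition_matrix)
  lin <- log(params$initial_probs)
  paths <- as.matrix(expand.grid(rep(list(1:4), n))[, n:1, drop = FALSE])
  score <- lin[paths[, 1]] + emis[cbind(1L, paths[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      score <- score + ltr[cbind(paths[, t - 1], paths[, t])] +
        emis[cbind(t, paths[, t])]
    }
  }
  best <- max(score)
  list(logp = best,
       paths = paths[score >= best - 1e-9, , drop = FALSE],
       unique = sum(score >= best - 1e-9) == 1L)
}

# Exact distribution of the longest success run in n iid Bernoulli(p) trials,
# by dynamic programming over (trials done, current trailing run), capped at
# r: returns P(max run >= r).
run_tail_dp <- function(n, p, r) {
  if (r == 0) return(1)
  if (r > n) return(0)
  # state: current trailing run length 0..r-1; absorbing "reached r"
  probs <- c(1, rep(0, r - 1))
  reached <- 0
  for (t in seq_len(n)) {
    nxt <- rep(0, r)
    for (k in seq_len(r)) {  # k-1 = trailing run before this trial
      pk <- probs[k]
      if (pk == 0) next
      if (k == r) reached <- reached + pk * p else nxt[k + 1] <- nxt[k + 1] + pk * p
      nxt[1] <- nxt[1] + pk * (1 - p)
    }
    probs <- nxt
  }
  reached
}

# Minimal simulation bundle used by several suites.
small_sim <- function(seed = 101L, error_rate = 0,
                      replicon_lengths = c(60000L, 20000L), ...) {
  cfg <- sim_config(seed = seed, replicon_lengths = replicon_lengths,
                    read_error_rate = error_rate, ...)
  simulate_counts(simulate_genome(cfg))
}
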
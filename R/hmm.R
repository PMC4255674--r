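# Four-state HMM over per-TA-site read counts, decoded with the Viterbi
# algorithm, plus the gene-level classification rules: modal state with
# severity tie-breaking, and an extreme-value (Gumbel) longest-run override
# for essential stretches.

# State order is fixed and meaningful: emission means must be strictly
# increasing along it, and Viterbi ties resolve toward the earlier state.
HMM_STATES <- c("ES", "GD", "NE", "GA")

#' Construct HMM parameters
#'
#' @param emission_means Named numeric vector of expected reads per site for
#'   `ES`, `GD`, `NE`, `GA`; must be strictly increasing in that order.
#'   Emissions are geometric on counts `c >= 0` with success probability
#'   `1 / (1 + mu)` (so the mean count in state `s` is `mu_s`).
#' @param transition_matrix 4x4 row-stochastic matrix (default: sticky, 0.98
#'   self-transition, remaining mass spread evenly).
#' @param initial_probs Initial state distribution (default uniform).
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(emission_means,
                       transition_matrix = NULL,
                       initial_probs = rep(0.25, 4L)) {
  emission_means <- emission_means[HMM_STATES]
  stopifnot(
    !anyNA(emission_means),
    all(diff(emission_means) > 0),
    all(emission_means > 0)
  )
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(0.02 / 3, 4L, 4L,
                                dimnames = list(HMM_STATES, HMM_STATES))
    diag(transition_matrix) <- 0.98
  }
  stopifnot(
    all(dim(transition_matrix) == c(4L, 4L)),
    all(abs(rowSums(transition_matrix) - 1) < 1e-12),
    all(transition_matrix > 0), all(transition_matrix < 1),
    length(initial_probs) == 4L,
    all(initial_probs > 0)
  )
  initial_probs <- initial_probs / sum(initial_probs)
  structure(
    list(states = HMM_STATES,
         emission_means = emission_means,
         emission_probs = 1 / (1 + emission_means),
         transition_matrix = transition_matrix,
         initial_probs = stats::setNames(initial_probs, HMM_STATES)),
    class = "hmm_params"
  )
}

#' Fit emission parameters from an insertion profile
#'
#' The neutral mean is anchored at the observed mean read count over occupied
#' sites of the replicon, `m`; growth-defective scales to `m/10` and
#' growth-advantage to `5m`. The essential mean is a near-zero constant
#' (default 0.01) rather than a fraction of `m`: biologically, reads at
#' essential sites should be (close to) absent regardless of sequencing
#' depth, and an essential mean tied to depth concedes so much zero-free
#' emission mass that essential and zero-inflated growth-defective regions
#' become statistically inseparable. Fitting is per replicon, so copy-number
#' differences in read depth between replicons cancel out of the
#' classification.
#'
#' @param counts Integer vector of per-site read counts for one replicon.
#' @param es_mean Emission mean of the essential state (default 0.01 reads
#'   per site).
#' @param min_sites Minimum number of TA sites required (default 100).
#' @param min_occupancy Minimum fraction of occupied sites required (default
#'   0.01); below this the library is not saturating enough for state calls.
#' @return An [hmm_params()] object.
#' @export
fit_emission_params <- function(counts, es_mean = 0.01, min_sites = 100L,
                                min_occupancy = 0.01) {
  occ <- counts > 0L
  if (length(counts) < min_sites || mean(occ) < min_occupancy) {
    stop("insufficient saturation: ", length(counts), " sites at occupancy ",
         signif(mean(occ), 3),
         "; check that the library saturates the replicon")
  }
  m <- mean(counts[occ])  # occupied counts are >= 1, so m >= 1 > 10 * es_mean
  hmm_params(c(ES = es_mean, GD = m / 10, NE = m, GA = 5 * m))
}

#' Viterbi decoding of an insertion profile
#'
#' Computes the maximum-probability hidden-state path in log space over all TA
#' sites of a replicon, independent of gene boundaries. Ties break toward the
#' earlier state in the order ES, GD, NE, GA.
#'
#' @param counts Integer vector of per-site read counts (length >= 1).
#' @param params An [hmm_params()] object.
#' @return Character vector of states, one per site.
#' @export
viterbi_decode <- function(counts, params) {
  n <- length(counts)
  stopifnot(n >= 1L, inherits(params, "hmm_params"))
  emis <- vapply(params$emission_probs,
                 function(p) stats::dgeom(counts, prob = p, log = TRUE),
                 numeric(n))
  emis <- matrix(emis, nrow = n)  # n x 4 even when n == 1
  ltr <- log(params$transition_matrix)
  delta <- log(params$initial_probs) + emis[1L, ]
  back <- matrix(0L, n, 4L)
  if (n > 1L) {
    for (t in 2:n) {
      cand <- delta + ltr  # cand[i, j] = delta[i] + log P(i -> j)
      best <- integer(4L)
      score <- numeric(4L)
      for (j in 1:4) {
        v <- cand[, j]
        best[j] <- which.max(v)  # first max: ties toward earlier state
        score[j] <- v[best[j]]
      }
      back[t, ] <- best
      delta <- score + emis[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) {
    for (t in n:2) path[t - 1L] <- back[t, path[t]]
  }
  HMM_STATES[path]
}

#' Extreme-value significance of the longest essential run in a gene
#'
#' The longest stretch of consecutive ES-decoded sites within the gene is
#' compared against the Gumbel-type approximation for the longest success run
#' in `n` Bernoulli(`p`) trials:
#' `P(R >= r) ~ 1 - exp(-(n - r + 1) * (1 - p) * p^r)`,
#' the expected number of run start positions times the per-start probability,
#' exponentiated in the usual extreme-value (rare-event) fashion. The
#' `n - r + 1` start count matters whenever `r` is an appreciable fraction of
#' `n`, which is exactly the regime of an essential stretch inside a short
#' gene.
#' The caller chooses the null probability `p`; [classify_replicon()] passes
#' the replicon-wide fraction of empty (zero-read) sites, i.e. the chance
#' that a site in a neutral gene merely *looks* uninserted, which is the
#' relevant chance hypothesis for a neutral gene showing an essential-looking
#' stretch. A run of length zero is never significant.
#'
#' @param states Character vector of decoded states for the gene's sites, in
#'   genomic order.
#' @param p_es Null per-trial success probability (0 < p < 1).
#' @param n_sites Number of trials for the null (defaults to the gene's site
#'   count).
#' @param alpha Significance level (default 0.05).
#' @return List with `run_length`, `p_value`, `significant`.
#' @export
longest_es_run_test <- function(states, p_es, n_sites = length(states),
                                alpha = 0.05) {
  stopifnot(p_es > 0, p_es < 1)
  r <- longest_run(states == "ES")
  if (r == 0L) {
    return(list(run_length = 0L, p_value = 1, significant = FALSE))
  }
  p <- 1 - exp(-(n_sites - r + 1) * (1 - p_es) * p_es^r)
  list(run_length = r, p_value = p, significant = p <= alpha)
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Classify one gene from its decoded sites
#'
#' Genes with no TA sites are `NoData`. Otherwise the class is the modal
#' Viterbi state over the gene's sites, ties broken in severity order
#' ES > GD > GA > NE, with an override to `ES` when the longest ES run is
#' significant under [longest_es_run_test()] (the override applies only to the
#' essential state). Insertion density and the mean read count over occupied
#' sites accompany the call.
#'
#' @param site_idx Integer indices of the gene's sites into the replicon's TA
#'   index (from [sites_per_gene()]).
#' @param states Decoded states for the whole replicon.
#' @param counts Read counts for the whole replicon.
#' @param p_es Null probability for the run test (see
#'   [longest_es_run_test()]).
#' @param locus Gene identifier carried through to the output.
#' @param alpha Significance level for the ES-run override. When a whole
#'   replicon is classified this should control the family-wise error over
#'   its genes (see [classify_replicon()]); the default 0.05 is the
#'   single-gene level.
#' @return One-row data.frame: `locus`, `phenotypic_class`, `n_sites`,
#'   `insertion_density`, `mean_read_count`, `modal_state`, `es_run_length`,
#'   `es_run_significant`.
#' @export
classify_gene <- function(site_idx, states, counts, p_es,
                          locus = NA_character_, alpha = 0.05) {
  n <- length(site_idx)
  if (n == 0L) {
    return(data.frame(
      locus = locus, phenotypic_class = "NoData", n_sites = 0L,
      insertion_density = NA_real_, mean_read_count = NA_real_,
      modal_state = NA_character_, es_run_length = 0L,
      es_run_significant = FALSE, stringsAsFactors = FALSE))
  }
  s <- states[site_idx]
  c_gene <- counts[site_idx]
  severity <- c(ES = 1L, GD = 2L, GA = 3L, NE = 4L)
  tab <- table(factor(s, levels = HMM_STATES))
  top <- names(tab)[tab == max(tab)]
  modal <- top[which.min(severity[top])]
  run <- longest_es_run_test(s, p_es, n_sites = n, alpha = alpha)
  cls <- if (run$significant) "ES" else modal
  occ <- c_gene[c_gene > 0L]
  data.frame(
    locus = locus,
    phenotypic_class = cls,
    n_sites = n,
    insertion_density = mean(c_gene > 0L),
    mean_read_count = if (length(occ)) mean(occ) else 0,
    modal_state = modal,
    es_run_length = run$run_length,
    es_run_significant = run$significant,
    stringsAsFactors = FALSE
  )
}

#' Classify every gene on one replicon
#'
#' Fits emission parameters on this replicon's profile (unless supplied),
#' Viterbi-decodes all its TA sites, then classifies each annotated gene.
#' The ES-run override is tested against the replicon's empty-site fraction
#' (the chance a site looks uninserted) at a Bonferroni-corrected level,
#' `alpha / n_genes`, so that a replicon of purely neutral genes flags
#' essentially none of them by chance.
#'
#' @param counts Read counts for the replicon.
#' @param positions TA positions for the replicon.
#' @param genes Annotation rows for this replicon.
#' @param params Optional [hmm_params()] override; default fits from `counts`.
#' @param alpha Family-wise significance level for the ES-run override
#'   (default 0.05, split across the replicon's genes).
#' @return List with `$gene_table` (one row per gene), `$states` (decoded site
#'   states), `$p_null` (run-test null probability), `$p_es` (fraction of
#'   sites decoded ES), `$params`, `$class_summary` (one-row count table).
#' @export
classify_replicon <- function(counts, positions, genes, params = NULL,
                              alpha = 0.05) {
  stopifnot(length(counts) == length(positions))
  if (is.null(params)) params <- fit_emission_params(counts)
  states <- viterbi_decode(counts, params)
  n <- length(states)
  p_es <- mean(states == "ES")
  # Chance probability that a site shows no insertion; clamped into the open
  # interval for degenerate (all-empty / all-occupied) profiles.
  p_null <- min(max(mean(counts == 0L), 1 / (2 * n)), 1 - 1 / (2 * n))
  alpha_gene <- alpha / max(1L, nrow(genes))
  site_map <- sites_per_gene(positions, genes)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    classify_gene(site_map[[i]], states, counts, p_null,
                  locus = genes$locus[i], alpha = alpha_gene)
  })
  gene_table <- data.table::rbindlist(rows)
  gene_table <- as.data.frame(gene_table)
  cls <- factor(gene_table$phenotypic_class,
                levels = c(HMM_STATES, "NoData"))
  summary <- data.frame(
    mapped_reads = sum(counts),
    as.list(table(cls)),
    gene_count = nrow(genes),
    stringsAsFactors = FALSE
  )
  list(gene_table = gene_table, states = states, p_null = p_null,
       p_es = p_es, params = params, class_summary = summary)
}

#' Classify every gene in a multi-replicon genome
#'
#' Each replicon is fitted and decoded independently, so differences in mean
#' read depth between replicons (e.g. from plasmid copy number) do not leak
#' into the classification.
#'
#' @param profiles Named list of count vectors per replicon.
#' @param ta TA index from [ta_site_index()].
#' @param annotation Full annotation data.frame.
#' @return List with `$gene_table` (all genes, with `replicon_id`),
#'   `$class_summary` (one row per replicon), `$states` (named list).
#' @export
classify_genome <- function(profiles, ta, annotation) {
  stopifnot(all(names(profiles) %in% names(ta)))
  tables <- list()
  summaries <- list()
  states <- list()
  for (r in names(profiles)) {
    genes_r <- annotation[annotation$replicon_id == r, , drop = FALSE]
    res <- classify_replicon(profiles[[r]], ta[[r]], genes_r)
    tab <- res$gene_table
    if (nrow(tab)) tab <- cbind(replicon_id = r, tab)
    tables[[r]] <- tab
    summaries[[r]] <- cbind(replicon_id = r, res$class_summary)
    states[[r]] <- res$states
  }
  list(
    gene_table = as.data.frame(data.table::rbindlist(tables)),
    class_summary = as.data.frame(data.table::rbindlist(summaries)),
    states = states
  )
}

#' Write the per-gene classification table as TSV
#'
#' Columns mirror the per-gene summary layout of this assay: locus, product,
#' potential insertions (TA sites), insertion density, mean read count over
#' occupied sites, phenotypic class, plus the supporting modal/run columns.
#'
#' @param gene_table data.frame from [classify_genome()] (`$gene_table`),
#'   optionally merged with annotation `product`.
#' @param path Output path.
#' @export
write_gene_table <- function(gene_table, path) {
  out <- gene_table
  for (col in c("insertion_density", "mean_read_count")) {
    out[[col]] <- round(out[[col]], 3L)
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write the per-replicon class summary as TSV
#'
#' @param class_summary data.frame from [classify_genome()]
#'   (`$class_summary`).
#' @param path Output path.
#' @export
write_class_summary <- function(class_summary, path) {
  data.table::fwrite(class_summary, path, sep = "\t")
  invisible(path)
}
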
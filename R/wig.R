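# variableStep WIG emission of per-TA-site values (read counts or integer
# state codes). One track per replicon, 1-based positions, zeros included so
# the file enumerates the full site universe and round-trips losslessly.

#' Write per-site values as a variableStep WIG file
#'
#' @param profiles Named list of numeric vectors, one per replicon, aligned to
#'   the TA index (zeros included).
#' @param ta TA index from [ta_site_index()].
#' @param path Output path.
#' @export
write_wig <- function(profiles, ta, path) {
  stopifnot(all(names(profiles) %in% names(ta)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in names(profiles)) {
    stopifnot(length(profiles[[r]]) == length(ta[[r]]))
    writeLines(sprintf("variableStep chrom=%s", r), con)
    if (length(ta[[r]])) {
      writeLines(paste(ta[[r]], profiles[[r]]), con)
    }
  }
  invisible(path)
}

#' Read a variableStep WIG file written by [write_wig()]
#'
#' @param path Input path.
#' @return List with `$profiles` (named list of numeric vectors) and
#'   `$positions` (named list of integer vectors).
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^variableStep\\b", lines)
  if (length(hdr) == 0L) stop("no variableStep track in ", path)
  ids <- sub(".*chrom=([^ ]+).*", "\\1", lines[hdr])
  bounds <- c(hdr, length(lines) + 1L)
  profiles <- vector("list", length(hdr))
  positions <- vector("list", length(hdr))
  names(profiles) <- ids
  names(positions) <- ids
  for (i in seq_along(hdr)) {
    block <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L,
                           length.out = max(0L, bounds[i + 1L] - bounds[i] - 1L))]
    if (length(block) == 0L) {
      positions[[i]] <- integer()
      profiles[[i]] <- numeric()
      next
    }
    m <- matrix(as.numeric(unlist(strsplit(block, " ", fixed = TRUE))),
                ncol = 2L, byrow = TRUE)
    positions[[i]] <- as.integer(m[, 1L])
    profiles[[i]] <- m[, 2L]
  }
  list(profiles = profiles, positions = positions)
}

#' Write decoded site states as an integer-coded WIG track
#'
#' States are coded ES=1, GD=2, NE=3, GA=4 for genome-browser viewing.
#'
#' @param states Named list of character state vectors per replicon.
#' @param ta TA index from [ta_site_index()].
#' @param path Output path.
#' @export
write_state_wig <- function(states, ta, path) {
  codes <- lapply(states, function(s) match(s, HMM_STATES))
  write_wig(codes, ta, path)
}
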
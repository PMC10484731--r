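# Independent brute-force quadruplex scanner used as the oracle for
# scanQuadMotifs(): a depth-first backtracking matcher built directly from
# the declarative pattern definition (k tracts of >= m bases separated by
# loops of 0..L bases over A/C/G/T, all quantifiers preferring longer),
# applied at every start position in order, selecting leftmost
# non-overlapping matches.  No regex engine involved.
oracleScan <- function(s, base, m, k, L) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  isBase <- ch == base
  validLoop <- ch %in% c("A", "C", "G", "T")
  # runFrom[p] = number of consecutive tract bases starting at p
  runFrom <- integer(n)
  r <- rle(isBase)
  pos <- 1L
  for (i in seq_along(r$lengths)) {
    len <- r$lengths[i]
    if (r$values[i]) runFrom[pos:(pos + len - 1L)] <- len:1L
    pos <- pos + len
  }
  # cumulative count of invalid loop chars for O(1) loop validity checks
  badCum <- c(0L, cumsum(!validLoop))
  loopOK <- function(from, to) {   # positions from..to all valid (or empty)
    from > to || badCum[to + 1L] - badCum[from] == 0L
  }
  failed <- matrix(FALSE, nrow = k, ncol = n)  # memoized failures (t, p)
  # returns match end if tracts t..k can be placed with tract t starting
  # exactly at p, exploring longest-first (the greedy order), else -1
  matchEnd <- function(p, t) {
    if (p > n || runFrom[p] < m) return(-1L)
    if (t == k) return(p + runFrom[p] - 1L)
    if (failed[t, p]) return(-1L)
    for (ell in seq.int(runFrom[p], m)) {
      q0 <- p + ell
      gmax <- min(L, n - q0)
      if (gmax < 0L) next
      for (g in seq.int(gmax, 0L)) {
        if (g > 0L && !loopOK(q0, q0 + g - 1L)) next
        e <- matchEnd(q0 + g, t + 1L)
        if (e > 0L) return(e)
      }
    }
    failed[t, p] <<- TRUE
    -1L
  }
  starts <- integer(0)
  widths <- integer(0)
  p <- 1L
  while (p <= n) {
    if (runFrom[p] >= m) {
      e <- matchEnd(p, 1L)
      if (e > 0L) {
        starts <- c(starts, p)
        widths <- c(widths, e - p + 1L)
        p <- e + 1L
        next
      }
    }
    p <- p + 1L
  }
  data.frame(start = starts, width = widths)
}

# oracle over a spec + strand, in the same coordinates scanQuadMotifs uses
oracleScanSpec <- function(s, spec, strandSym) {
  b <- if (strandSym == "+") spec@base else c(C = "G", G = "C")[[spec@base]]
  oracleScan(s, b, spec@tractLength, spec@nTracts, spec@maxLoop)
}
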
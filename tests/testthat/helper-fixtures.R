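# shared fixtures, built in code

ref_fmt <- simulate_reference_tac(schedule = frame_schedule("FMT"))
ref_rac <- simulate_reference_tac(schedule = frame_schedule("RAC"))

# small single-region box phantom: label 1 inside a zero background
box_labels <- function(shape = c(12, 12, 6), lo = c(4, 4, 2), hi = c(8, 9, 5)) {
  lab <- array(0L, shape)
  lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  lab
}

# independent connected-components labeller (used as oracle): repeated
# dilation-style region growing over a logical array, written without the
# package's BFS
oracle_max_cluster <- function(mask, connectivity = 6) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = nz == 1, "18" = nz >= 1 & nz <= 2,
                      "26" = nz >= 1), , drop = FALSE]
  remaining <- which(mask)
  best <- 0L
  while (length(remaining) > 0L) {
    grown <- remaining[1]
    repeat {
      cur <- arrayInd(grown, d)
      cand <- unique(unlist(lapply(seq_len(nrow(offs)), function(o) {
        p <- sweep(cur, 2, offs[o, ], "+")
        ok <- p[, 1] >= 1 & p[, 2] >= 1 & p[, 3] >= 1 &
          p[, 1] <= d[1] & p[, 2] <= d[2] & p[, 3] <= d[3]
        p <- p[ok, , drop = FALSE]
        p[, 1] + d[1] * ((p[, 2] - 1) + d[2] * (p[, 3] - 1))
      })))
      nxt <- union(grown, intersect(cand, remaining))
      if (length(nxt) == length(grown)) break
      grown <- nxt
    }
    best <- max(best, length(grown))
    remaining <- setdiff(remaining, grown)
  }
  best
}
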
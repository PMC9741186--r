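# Independent oracle for allocate_step: plain loops, no shared code paths.
# Growing classes claim cells of shrinking classes in globally descending
# claimant suitability; each shrinking class releases at most its surplus.
# Assumes tie-free suitability (callers jitter), so no RNG is needed.
brute_force_allocate <- function(grid, n_tgt, suit) {
  sc <- grid$scheme
  v <- grid$values
  cls <- match(v, sc$codes)
  cur <- tabulate(cls[!is.na(cls)], nbins = length(sc$codes))
  delta <- n_tgt - cur
  need <- pmax(delta, 0)
  cap <- pmax(-delta, 0)
  at <- function(ce, k) suit[(ce - 1) %% nrow(v) + 1,
                             (ce - 1) %/% nrow(v) + 1, k]
  pool <- which(!is.na(cls) & cap[cls] > 0)
  cand <- NULL
  for (ce in pool)
    for (k in which(need > 0))
      cand <- rbind(cand, c(ce, k, at(ce, k)))
  if (is.null(cand)) return(v)
  cand <- cand[order(-cand[, 3]), , drop = FALSE]
  taken <- c()
  for (r in seq_len(nrow(cand))) {
    ce <- cand[r, 1]; k <- cand[r, 2]; k0 <- cls[ce]
    if (need[k] > 0 && cap[k0] > 0 && !(ce %in% taken)) {
      v[ce] <- sc$codes[k]
      need[k] <- need[k] - 1
      cap[k0] <- cap[k0] - 1
      taken <- c(taken, ce)
    }
  }
  v
}
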
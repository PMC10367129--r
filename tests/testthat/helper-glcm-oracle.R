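# Independent brute-force GLCM oracle: enumerates every pixel pair
# explicitly, accumulating a symmetric co-occurrence matrix per offset.
# Deliberately loop-based and structured differently from the package
# implementation.

glcm_oracle <- function(img, mask, levels, granularity = 1L) {
  vals <- img[mask]
  mn <- min(vals); mx <- max(vals)
  if (mx > mn) {
    q <- pmin(floor((img - mn) / (mx - mn) * levels), levels - 1L)
    q[q < 0] <- 0L
  } else {
    q <- img * 0L
  }
  offsets <- list(c(0L, granularity), c(granularity, 0L),
                  c(granularity, granularity), c(granularity, -granularity))
  per <- matrix(NA_real_, 4, 4,
                dimnames = list(NULL, c("homogeneity", "correlation",
                                        "entropy", "contrast")))
  for (k in seq_along(offsets)) {
    o <- offsets[[k]]
    acc <- matrix(0, levels, levels)
    for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img) &&
          mask[r, cc] && mask[r2, c2]) {
        i <- q[r, cc] + 1L; j <- q[r2, c2] + 1L
        acc[i, j] <- acc[i, j] + 1
        acc[j, i] <- acc[j, i] + 1
      }
    }
    if (sum(acc) == 0) next
    p <- acc / sum(acc)
    iv <- 0:(levels - 1L)
    io <- matrix(iv, levels, levels); jo <- t(io)
    hom <- sum(p / (1 + abs(io - jo)))
    con <- sum(p * (io - jo)^2)
    pp <- p[p > 0]
    ent <- -sum(pp * log(pp))
    mu <- sum(iv * rowSums(p))
    s2 <- sum((iv - mu)^2 * rowSums(p))
    cr <- if (s2 <= 0) 0 else (sum(p * io * jo) - mu^2) / s2
    per[k, ] <- c(hom, cr, ent, con)
  }
  ok <- stats::complete.cases(per)
  if (!any(ok)) return(NULL)
  per <- per[ok, , drop = FALSE]
  out <- list()
  for (s in colnames(per)) {
    out[[paste0("h_", s, "_mean")]] <- mean(per[, s])
    out[[paste0("h_", s, "_std")]] <-
      if (nrow(per) > 1) stats::sd(per[, s]) else 0
  }
  out
}
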
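# observed information by central finite differences on the two parameters
pdo_fit_hessian <- function(fit, pairs, h = 1e-3) {
  nms <- setdiff(names(fit$params), "threshold")
  ll <- function(par) {
    params <- as.list(par); names(params) <- nms
    op <- make_pdo(fit$family, params, max(pairs$true_count),
                   y_max = nrow(fit$pdo$C) - 1)
    sum(log(pmax(op$C[cbind(match_y(pairs$observed, op),
                            pairs$true_count + 1)], 1e-300)))
  }
  p0 <- unlist(fit$params[nms])
  H <- matrix(0, length(p0), length(p0), dimnames = list(nms, nms))
  for (i in seq_along(p0)) for (j in seq_along(p0)) {
    hi <- h * max(abs(p0[i]), 1); hj <- h * max(abs(p0[j]), 1)
    pp <- p0; pp[i] <- pp[i] + hi; pp[j] <- pp[j] + hj
    pm <- p0; pm[i] <- pm[i] + hi; pm[j] <- pm[j] - hj
    mp <- p0; mp[i] <- mp[i] - hi; mp[j] <- mp[j] + hj
    mm <- p0; mm[i] <- mm[i] - hi; mm[j] <- mm[j] - hj
    H[i, j] <- -(ll(pp) - ll(pm) - ll(mp) + ll(mm)) / (4 * hi * hj)
  }
  (H + t(H)) / 2
}

match_y <- function(y, op) snapfim:::match_observable(y, op)
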
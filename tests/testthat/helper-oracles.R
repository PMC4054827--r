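# independent oracles shared across test files

# exact hypergeometric upper-tail sum via log-space binomial coefficients
hyper_upper_oracle <- function(obs, N, K, n) {
  if (obs > min(K, n)) return(0)
  kk <- obs:min(K, n)
  terms <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  mx <- max(terms)
  exp(mx) * sum(exp(terms - mx))
}

# brute-force enumeration of maximal same-sign above-threshold runs
brute_force_dmrs <- function(sm, clusters, thr, min_probes) {
  hits <- list()
  for (cid in unique(clusters$cluster_id)) {
    i <- which(clusters$cluster_id == cid)
    for (a in seq_along(i)) for (b in a:length(i)) {
      seg <- sm[i[a:b]]
      if (length(seg) >= min_probes && all(abs(seg) > thr) &&
          (all(seg > 0) || all(seg < 0))) {
        left_ok <- a == 1 || !(abs(sm[i[a - 1]]) > thr &&
                                 sign(sm[i[a - 1]]) == sign(seg[1]))
        right_ok <- b == length(i) || !(abs(sm[i[b + 1]]) > thr &&
                                          sign(sm[i[b + 1]]) == sign(seg[1]))
        if (left_ok && right_ok)
          hits[[length(hits) + 1L]] <- clusters$probe_id[i[a:b]]
      }
    }
  }
  hits
}
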
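# Independent oracles used against the package implementation.

# Exhaustive HMM oracle: enumerate all 2^n state paths, score each by direct
# probability products (uniform init, Haldane transitions, symmetric
# emissions), and return the argmax set and exact posteriors.
oracle_hmm <- function(obs, pos, epsilon, rate) {
  n <- length(obs)
  states <- c("I", "D")
  emit <- function(o, s) {
    if (is.na(o)) return(1)
    if ((o == "i" && s == "I") || (o == "d" && s == "D")) 1 - epsilon
    else epsilon
  }
  gaps <- diff(pos)
  tsw <- 0.5 * (1 - exp(-2 * rate * gaps))
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))[, n:1, drop = FALSE]
  logp <- apply(paths, 1, function(p) {
    lp <- log(0.5) + log(emit(obs[1], states[p[1]]))
    for (k in seq_len(n - 1)) {
      t <- tsw[k]
      lp <- lp + log(if (p[k] == p[k + 1]) 1 - t else t) +
        log(emit(obs[k + 1], states[p[k + 1]]))
    }
    lp
  })
  best <- max(logp)
  argmax <- paths[logp >= best - 1e-9, , drop = FALSE]
  # site-wise posteriors by summing path probabilities
  w <- exp(logp - best)
  post_I <- vapply(seq_len(n), function(k) {
    sum(w[paths[, k] == 1]) / sum(w)
  }, numeric(1))
  list(logp = logp, best = best,
       argmax = matrix(states[argmax], nrow = nrow(argmax)),
       post_I = post_I)
}

oracle_path_logprob <- function(path, obs, pos, epsilon, rate) {
  p <- match(path, c("I", "D"))
  o <- oracle_hmm(obs, pos, epsilon, rate) # small n only
  idx <- apply(o$argmax, 1, function(a) all(a == path))
  list(oracle = o, is_argmax = any(idx))
}

# Rule-table Mendelian oracle, written from the segregation rules directly
# (independent of the package's assignment-enumeration implementation).
# Genotypes are dosage codes; returns list(pat, mat, flag).
oracle_phase <- function(f, m, c) {
  if (is.na(c)) return(list(pat = NA, mat = NA, flag = "missing"))
  hom_allele <- function(g) if (g == 0L) "ref" else "alt"
  other <- function(a) if (a == "ref") "alt" else "ref"
  child_has <- function(a) {
    if (c == 1L) TRUE else (c == 0L) == (a == "ref")
  }
  if (f != 1L && m != 1L) { # uninformative: both hom, alleles forced
    p <- hom_allele(f); mt <- hom_allele(m)
    expected <- (p == "alt") + (mt == "alt")
    if (c == expected) list(pat = p, mat = mt, flag = "ok")
    else list(pat = NA, mat = NA, flag = "mendelian_error")
  } else if (f == 1L && m == 1L) { # double het
    if (c == 1L) list(pat = NA, mat = NA, flag = "unphaseable")
    else {
      a <- if (c == 0L) "ref" else "alt"
      list(pat = a, mat = a, flag = "ok")
    }
  } else if (m == 1L) { # maternal informative: father hom x
    x <- hom_allele(f)
    if (!child_has(x)) list(pat = NA, mat = NA, flag = "mendelian_error")
    else {
      mt <- if (c == 1L) other(x) else hom_allele(c)
      list(pat = x, mat = mt, flag = "ok")
    }
  } else { # paternal informative: mother hom x
    x <- hom_allele(m)
    if (!child_has(x)) list(pat = NA, mat = NA, flag = "mendelian_error")
    else {
      p <- if (c == 1L) other(x) else hom_allele(c)
      list(pat = p, mat = x, flag = "ok")
    }
  }
}
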
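# Two-state HMM refinement of i/d observation tracks (step 2 of the method).
#
# Hidden states: I (embryo shares the reference child's parental haplotype at
# this site) and D (it does not). Raw i/d observations flip at isolated sites
# because whole-genome amplification of a single cell introduces allelic
# drop-out and replication errors, but a true state switch requires a meiotic
# crossover, which is rare at the sub-megabase scale. Emissions absorb the
# artifact rate (epsilon); transitions scale with inter-site distance through
# the Haldane map function, so the decoded path is piecewise constant with
# switches only where the data support a crossover.

#' HMM parameters for haplotype-block refinement
#'
#' @param epsilon Probability of observing the discordant symbol given the
#'   true state (per informative site). Absorbs allelic drop-out plus
#'   amplification error; default 0.10.
#' @param recomb_rate_per_bp Expected crossovers per bp used in the
#'   distance-dependent transition probability. Default 1e-8 (~1 cM/Mb).
#' @param min_block_span_bp Blocks spanning less than this AND containing
#'   fewer than `min_block_sites` sites are merged into their flanks after
#'   decoding. Default 500 kb, the scale at which isolated state flips are
#'   biologically implausible.
#' @param min_block_sites Site-count partner of `min_block_span_bp`, also the
#'   minimum supporting sites for a confident diagnosis. Default 25.
#' @param decode_mode `"viterbi"` (joint most probable path) or `"posterior"`
#'   (site-wise maximum of the smoothed posterior).
#' @return An `hmm_parameters` list.
#' @export
hmm_parameters <- function(epsilon = 0.10,
                           recomb_rate_per_bp = 1e-8,
                           min_block_span_bp = 5e5,
                           min_block_sites = 25L,
                           decode_mode = c("viterbi", "posterior")) {
  decode_mode <- match.arg(decode_mode)
  stopifnot(epsilon > 0, epsilon < 0.5,
            recomb_rate_per_bp > 0,
            min_block_span_bp >= 0,
            min_block_sites >= 0)
  structure(list(epsilon = epsilon,
                 recomb_rate_per_bp = recomb_rate_per_bp,
                 min_block_span_bp = min_block_span_bp,
                 min_block_sites = as.integer(min_block_sites),
                 decode_mode = decode_mode),
            class = "hmm_parameters")
}

#' Distance-dependent transition matrix
#'
#' The probability that the I/D state switches across a gap of `gap_bp` bases
#' is the Haldane map function
#' \eqn{t = 0.5 (1 - e^{-2 r \cdot gap})}, with `r` the recombination rate per
#' bp: zero at zero distance, approaching 1/2 (free recombination) at large
#' distances.
#'
#' @param gap_bp Non-negative inter-site distance in bp.
#' @param params [hmm_parameters()].
#' @return 2x2 stochastic matrix with rows/columns `I`, `D`.
#' @export
transition_matrix <- function(gap_bp, params = hmm_parameters()) {
  stopifnot(gap_bp >= 0)
  t <- switch_probability(gap_bp, params$recomb_rate_per_bp)
  matrix(c(1 - t, t, t, 1 - t), nrow = 2, byrow = TRUE,
         dimnames = list(c("I", "D"), c("I", "D")))
}

switch_probability <- function(gap_bp, rate) {
  0.5 * (1 - exp(-2 * rate * gap_bp))
}

#' Emission probability
#'
#' Symmetric error model: the concordant symbol is seen with probability
#' `1 - epsilon`, the discordant one with `epsilon`; a missing observation is
#' uninformative (probability 1 under both states, so it cancels).
#'
#' @param obs `"i"`, `"d"`, or NA/`"missing"`.
#' @param state `"I"` or `"D"`.
#' @param params [hmm_parameters()].
#' @return Probability of `obs` given `state`.
#' @export
emission_prob <- function(obs, state, params = hmm_parameters()) {
  stopifnot(state %in% c("I", "D"))
  if (is.na(obs) || obs == "missing") return(1)
  stopifnot(obs %in% c("i", "d"))
  concordant <- (obs == "i" & state == "I") | (obs == "d" & state == "D")
  if (concordant) 1 - params$epsilon else params$epsilon
}

# log-emission matrix (n x 2, columns I, D) for an obs vector
log_emissions <- function(obs, params) {
  le <- matrix(0, nrow = length(obs), ncol = 2,
               dimnames = list(NULL, c("I", "D")))
  conc <- log(1 - params$epsilon)
  disc <- log(params$epsilon)
  is_i <- !is.na(obs) & obs == "i"
  is_d <- !is.na(obs) & obs == "d"
  le[is_i, 1] <- conc; le[is_i, 2] <- disc
  le[is_d, 1] <- disc; le[is_d, 2] <- conc
  le
}

check_track <- function(track) {
  if (nrow(track) == 0L) stop("empty observation track: no informative sites")
  if (length(unique(track$chrom)) != 1L) {
    stop("tracks are decoded per chromosome; split multi-chromosome input")
  }
  invisible(track)
}

#' Viterbi decoding of an observation track
#'
#' Maximum-probability I/D state path under a uniform initial distribution,
#' distance-dependent transitions and the symmetric emission model, computed
#' in log space. Ties are broken deterministically toward state I.
#'
#' @param track An `observation_track` (single chromosome).
#' @param params [hmm_parameters()].
#' @return Character vector of states (`"I"`/`"D"`), one per track site.
#' @export
viterbi_decode <- function(track, params = hmm_parameters()) {
  check_track(track)
  n <- nrow(track)
  le <- log_emissions(track$obs, params)
  delta <- matrix(-Inf, nrow = n, ncol = 2)
  psi <- matrix(1L, nrow = n, ncol = 2)
  delta[1, ] <- log(0.5) + le[1, ]
  if (n > 1) {
    gaps <- diff(track$pos)
    for (k in 2:n) {
      t <- switch_probability(gaps[k - 1], params$recomb_rate_per_bp)
      lstay <- log1p(-t)
      lswitch <- log(t)
      # candidate scores for arriving in I (col 1) and D (col 2)
      cand_I <- c(delta[k - 1, 1] + lstay, delta[k - 1, 2] + lswitch)
      cand_D <- c(delta[k - 1, 1] + lswitch, delta[k - 1, 2] + lstay)
      psi[k, 1] <- if (cand_I[1] >= cand_I[2]) 1L else 2L # tie -> from I
      psi[k, 2] <- if (cand_D[1] >= cand_D[2]) 1L else 2L
      delta[k, 1] <- cand_I[psi[k, 1]] + le[k, 1]
      delta[k, 2] <- cand_D[psi[k, 2]] + le[k, 2]
    }
  }
  path <- integer(n)
  path[n] <- if (delta[n, 1] >= delta[n, 2]) 1L else 2L # tie -> I
  if (n > 1) {
    for (k in (n - 1):1) path[k] <- psi[k + 1, path[k + 1]]
  }
  c("I", "D")[path]
}

#' Forward-backward smoothing of an observation track
#'
#' Exact smoothed posteriors with per-site scaling.
#'
#' @param track An `observation_track` (single chromosome).
#' @param params [hmm_parameters()].
#' @return data.frame with `posterior_I` and `posterior_D`
#'   (`posterior_I + posterior_D = 1` at every site).
#' @export
forward_backward <- function(track, params = hmm_parameters()) {
  check_track(track)
  n <- nrow(track)
  em <- exp(log_emissions(track$obs, params))
  gaps <- if (n > 1) diff(track$pos) else numeric(0)
  alpha <- matrix(0, n, 2)
  scale <- numeric(n)
  a <- c(0.5, 0.5) * em[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  for (k in seq_len(n - 1) + 1) {
    t <- switch_probability(gaps[k - 1], params$recomb_rate_per_bp)
    pred <- c(alpha[k - 1, 1] * (1 - t) + alpha[k - 1, 2] * t,
              alpha[k - 1, 1] * t + alpha[k - 1, 2] * (1 - t))
    a <- pred * em[k, ]
    scale[k] <- sum(a)
    alpha[k, ] <- a / scale[k]
  }
  beta <- matrix(0, n, 2)
  beta[n, ] <- 1
  if (n > 1) {
    for (k in (n - 1):1) {
      t <- switch_probability(gaps[k], params$recomb_rate_per_bp)
      nb <- beta[k + 1, ] * em[k + 1, ]
      beta[k, ] <- c(nb[1] * (1 - t) + nb[2] * t,
                     nb[1] * t + nb[2] * (1 - t)) / scale[k + 1]
    }
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  data.frame(posterior_I = g[, 1], posterior_D = g[, 2])
}

#' Decode an observation track into a refined state sequence
#'
#' Runs the decoder selected by `params$decode_mode` and annotates every site
#' with its smoothed posterior.
#'
#' @param track An `observation_track` (single chromosome).
#' @param params [hmm_parameters()].
#' @return A `state_sequence`: the track plus `state` and `posterior_I`
#'   columns.
#' @export
decode_track <- function(track, params = hmm_parameters()) {
  post <- forward_backward(track, params)
  state <- if (params$decode_mode == "viterbi") {
    viterbi_decode(track, params)
  } else {
    ifelse(post$posterior_I >= 0.5, "I", "D") # tie -> I
  }
  out <- cbind(as.data.frame(track), state = state,
               posterior_I = post$posterior_I)
  structure(out,
            embryo_id = attr(track, "embryo_id"),
            origin = attr(track, "origin"),
            class = c("state_sequence", "data.frame"))
}

#' Segment a decoded state sequence into haplotype blocks
#'
#' Run-length encodes the I/D states into blocks anchored at informative-site
#' positions. Blocks spanning less than `min_block_span_bp` AND containing
#' fewer than `min_block_sites` sites are absorbed into their flanking state
#' (smallest span first; an edge block merges into its single neighbour).
#' Crossover breakpoints are reported as the open interval between the last
#' site of one block and the first site of the next.
#'
#' @param seq A `state_sequence` from [decode_track()].
#' @param params [hmm_parameters()].
#' @return A `block_segmentation`: list with `blocks` (chrom, start_pos,
#'   end_pos, state, n_sites, mean_posterior), `breakpoints` (chrom, left_pos,
#'   right_pos) and `sites` (the input with post-merge states).
#' @export
segment_blocks <- function(seq, params = hmm_parameters()) {
  stopifnot(nrow(seq) >= 1)
  pos <- seq$pos
  state <- seq$state

  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(state = r$values, start = starts, end = ends,
                     stringsAsFactors = FALSE)

  repeat {
    if (nrow(runs) <= 1L) break
    span <- pos[runs$end] - pos[runs$start]
    nsites <- runs$end - runs$start + 1L
    small <- span < params$min_block_span_bp & nsites < params$min_block_sites
    if (!any(small)) break
    j <- which(small)[which.min(span[small])]
    # relabel the small run to its flank state; interior flanks always agree
    # (states alternate), edge runs take the single neighbour's state
    flank <- if (j == 1L) 2L else j - 1L
    runs$state[j] <- runs$state[flank]
    # fuse adjacent equal-state runs
    keep <- c(TRUE, runs$state[-1] != runs$state[-nrow(runs)])
    grp <- cumsum(keep)
    runs <- data.frame(state = tapply(runs$state, grp, `[`, 1L),
                       start = as.integer(tapply(runs$start, grp, min)),
                       end = as.integer(tapply(runs$end, grp, max)),
                       stringsAsFactors = FALSE)
    rownames(runs) <- NULL
  }

  refined <- rep(runs$state, runs$end - runs$start + 1L)
  sites <- as.data.frame(seq)
  sites$state <- refined

  blocks <- data.frame(
    chrom = seq$chrom[runs$start],
    start_pos = pos[runs$start],
    end_pos = pos[runs$end],
    state = runs$state,
    n_sites = runs$end - runs$start + 1L,
    mean_posterior = vapply(seq_len(nrow(runs)), function(i) {
      p <- seq$posterior_I[runs$start[i]:runs$end[i]]
      if (runs$state[i] == "I") mean(p) else mean(1 - p)
    }, numeric(1)),
    stringsAsFactors = FALSE)

  nb <- nrow(blocks)
  breakpoints <- if (nb > 1L) {
    data.frame(chrom = blocks$chrom[-nb],
               left_pos = blocks$end_pos[-nb],
               right_pos = blocks$start_pos[-1],
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), left_pos = integer(0),
               right_pos = integer(0), stringsAsFactors = FALSE)
  }

  structure(list(blocks = blocks, breakpoints = breakpoints, sites = sites),
            embryo_id = attr(seq, "embryo_id"),
            origin = attr(seq, "origin"),
            class = "block_segmentation")
}

#' @export
print.block_segmentation <- function(x, ...) {
  cat("block_segmentation:", attr(x, "embryo_id"), "/", attr(x, "origin"),
      "-", nrow(x$blocks), "block(s),", nrow(x$breakpoints),
      "breakpoint(s)\n")
  print(x$blocks)
  invisible(x)
}

#' Refine one embryo/origin track end to end
#'
#' Convenience wrapper: [decode_track()] then [segment_blocks()], applied per
#' chromosome and recombined.
#'
#' @param track An `observation_track`, possibly spanning several chromosomes.
#' @param params [hmm_parameters()].
#' @return A `block_segmentation` covering all chromosomes in the track.
#' @export
refine_track <- function(track, params = hmm_parameters()) {
  chroms <- unique(track$chrom)
  parts <- lapply(chroms, function(ch) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    rownames(sub) <- NULL
    sub <- structure(sub, embryo_id = attr(track, "embryo_id"),
                     origin = attr(track, "origin"),
                     class = class(track))
    segment_blocks(decode_track(sub, params), params)
  })
  structure(list(
    blocks = do.call(rbind, lapply(parts, `[[`, "blocks")),
    breakpoints = do.call(rbind, lapply(parts, `[[`, "breakpoints")),
    sites = do.call(rbind, lapply(parts, `[[`, "sites"))),
    embryo_id = attr(track, "embryo_id"),
    origin = attr(track, "origin"),
    class = "block_segmentation")
}
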
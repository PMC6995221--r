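# Build a block_segmentation directly: blocks over [1, 90] Mb with a given
# state at the 45-46 Mb locus and dense supporting sites.
make_seg <- function(states = c("I", "D"), switch_at = 60e6,
                     chrom = "chr16", embryo_id = "E1",
                     spacing = 5e4) {
  pos <- seq(1e6, 89e6, by = spacing)
  state <- ifelse(pos <= switch_at, states[1],
                  if (length(states) > 1) states[2] else states[1])
  if (length(states) == 1) state <- rep(states, length(pos))
  sites <- data.frame(chrom = chrom, pos = pos, obs = tolower(state),
                      state = state, posterior_I = ifelse(state == "I",
                                                          0.99, 0.01),
                      stringsAsFactors = FALSE)
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  blocks <- data.frame(chrom = chrom, start_pos = pos[starts],
                       end_pos = pos[ends], state = r$values,
                       n_sites = r$lengths,
                       mean_posterior = 0.99, stringsAsFactors = FALSE)
  nb <- nrow(blocks)
  breakpoints <- if (nb > 1) data.frame(chrom = chrom,
                                        left_pos = blocks$end_pos[-nb],
                                        right_pos = blocks$start_pos[-1])
  else data.frame(chrom = character(0), left_pos = numeric(0),
                  right_pos = numeric(0))
  structure(list(blocks = blocks, breakpoints = breakpoints, sites = sites),
            embryo_id = embryo_id, origin = "maternal",
            class = "block_segmentation")
}

locus_dom <- disease_locus("chr16", 45e6, 46e6,
                           mode = "autosomal_dominant",
                           transmitting_parents = "maternal")

test_that("block state at the locus determines the carrier call", {
  p <- hmm_parameters()
  st <- call_origin_status(make_seg("I"), locus_dom, "maternal", p)
  expect_equal(st$call, "carries_mutation")
  expect_equal(st$state_at_locus, "I")
  expect_gt(st$mean_posterior, 0.9)
  expect_equal(call_origin_status(make_seg("D"), locus_dom, "maternal",
                                  p)$call,
               "free_of_mutation")
  # a breakpoint away from the locus does not affect the call
  expect_equal(call_origin_status(make_seg(c("I", "D"), switch_at = 70e6),
                                  locus_dom, "maternal", p)$call,
               "carries_mutation")
})

test_that("a breakpoint inside the locus is a recombinant no-call", {
  seg <- make_seg(c("I", "D"), switch_at = 45.4e6)
  st <- call_origin_status(seg, locus_dom, "maternal", hmm_parameters())
  expect_equal(st$call, "recombinant_no_call")
})

test_that("reversing reference_carries flips carries/free and nothing else", {
  flipped <- disease_locus("chr16", 45e6, 46e6,
                           mode = "autosomal_dominant",
                           transmitting_parents = "maternal",
                           reference_carries = c(maternal = FALSE))
  p <- hmm_parameters()
  expect_equal(call_origin_status(make_seg("I"), flipped, "maternal", p)$call,
               "free_of_mutation")
  expect_equal(call_origin_status(make_seg("D"), flipped, "maternal", p)$call,
               "carries_mutation")
  seg <- make_seg(c("I", "D"), switch_at = 45.4e6)
  expect_equal(call_origin_status(seg, flipped, "maternal", p)$call,
               "recombinant_no_call")
})

test_that("insufficient support or an absent chromosome yields a no-call", {
  p <- hmm_parameters()
  sparse <- make_seg("I", spacing = 5e6)  # < 25 sites in the window
  expect_equal(call_origin_status(sparse, locus_dom, "maternal", p)$call,
               "no_call_insufficient_data")
  other <- disease_locus("chr2", 45e6, 46e6, mode = "autosomal_dominant",
                         transmitting_parents = "maternal")
  expect_warning(st <- call_origin_status(make_seg("I"), other,
                                          "maternal", p),
                 "no haplotype blocks")
  expect_equal(st$call, "no_call_insufficient_data")
})

test_that("overall status combines per-origin calls by inheritance mode", {
  expect_equal(combine_calls(c(maternal = "carries_mutation"),
                             "autosomal_dominant"), "affected")
  expect_equal(combine_calls(c(maternal = "free_of_mutation"),
                             "autosomal_dominant"), "unaffected")
  expect_equal(combine_calls(c(maternal = "recombinant_no_call"),
                             "autosomal_dominant"), "no_call")
  expect_equal(combine_calls(c(paternal = "carries_mutation",
                               maternal = "carries_mutation"),
                             "autosomal_recessive"), "affected")
  expect_equal(combine_calls(c(paternal = "carries_mutation",
                               maternal = "free_of_mutation"),
                             "autosomal_recessive"), "carrier")
  expect_equal(combine_calls(c(paternal = "free_of_mutation",
                               maternal = "free_of_mutation"),
                             "autosomal_recessive"), "unaffected")
  expect_equal(combine_calls(c(paternal = "no_call_insufficient_data",
                               maternal = "carries_mutation"),
                             "autosomal_recessive"), "no_call")
})

test_that("X-linked modes are rejected with a clear error", {
  expect_error(disease_locus("chrX", 1e6, 2e6, mode = "x_linked_recessive",
                             transmitting_parents = "maternal"),
               "X-linked")
})

test_that("family summary counts statuses and orders embryos deterministically", {
  segs <- list(E2 = make_seg("D", embryo_id = "E2"),
               E1 = make_seg("I", embryo_id = "E1"))
  reports <- lapply(segs, function(s)
    diagnose_embryo(list(maternal = s), locus_dom))
  s <- summarize_family(reports)
  expect_equal(s$n_embryos, 2)
  expect_equal(s$status_counts$affected, 1L)
  expect_equal(s$status_counts$unaffected, 1L)
  expect_equal(unname(vapply(s$embryos, `[[`, character(1), "embryo_id")),
               c("E1", "E2"))
  # single embryo with no usable data
  sparse <- make_seg("I", spacing = 5e6)
  r <- diagnose_embryo(list(maternal = sparse), locus_dom)
  s1 <- summarize_family(list(r))
  expect_equal(s1$status_counts$no_call, 1L)
})

test_that("diagnosis is invariant to adding uninformative sites", {
  cfg <- simulation_config(n_sites = 1200, chrom_length_bp = 9e7,
                           n_embryos = 2, p_ado = 0, p_err = 0, p_missing = 0,
                           locus = locus_dom, seed = 31)
  fam <- simulate_family(cfg)
  fd1 <- diagnose_family(fam$gm, locus_dom)
  # inject double-het and uninformative rows (they never enter any track)
  gm2 <- fam$gm
  extra <- data.frame(chrom = "chr16", pos = c(44.95e6, 45.55e6),
                      site_id = c("x1", "x2"), ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  gm2$sites <- rbind(gm2$sites, extra)
  gm2$gt <- rbind(gm2$gt, matrix(c(1L, 1L, 1L, 1L, 1L,
                                   0L, 0L, 0L, 0L, 0L),
                                 nrow = 2, byrow = TRUE))
  ord <- order(gm2$sites$pos)
  gm2$sites <- gm2$sites[ord, ]
  gm2$gt <- gm2$gt[ord, ]
  fd2 <- diagnose_family(gm2, locus_dom)
  expect_equal(fd2$summary$status_counts, fd1$summary$status_counts)
  expect_equal(
    vapply(fd2$reports, `[[`, character(1), "overall_status"),
    vapply(fd1$reports, `[[`, character(1), "overall_status"))
})
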
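# Carrier-status diagnosis at the disease locus.
#
# An embryo carries the parental mutation when it inherited the same parental
# haplotype block as the (affected) reference child at the mutation position;
# a crossover breakpoint inside the locus interval makes the linkage-based
# call impossible (recombinant no-call).

ORIGIN_CALLS <- c("carries_mutation", "free_of_mutation",
                  "recombinant_no_call", "no_call_insufficient_data")

#' Describe a disease locus
#'
#' @param chrom Chromosome label matching the input VCF.
#' @param start_pos,end_pos 1-based closed interval of the gene/locus.
#' @param mode `"autosomal_dominant"` or `"autosomal_recessive"`. X-linked
#'   modes are rejected: the method phases autosomes through both parents.
#' @param transmitting_parents Subset of `c("paternal", "maternal")`: which
#'   parent(s) transmit the mutation.
#' @param flank_bp Window half-width around the locus used to count supporting
#'   informative sites. Default 2 Mb.
#' @param reference_carries Named logical per transmitting origin: does the
#'   reference child carry the mutation on that origin's haplotype? Defaults
#'   to TRUE for every transmitting parent (affected child as reference).
#' @return A `disease_locus` list.
#' @export
disease_locus <- function(chrom, start_pos, end_pos,
                          mode = c("autosomal_dominant", "autosomal_recessive"),
                          transmitting_parents,
                          flank_bp = 2e6,
                          reference_carries = NULL) {
  if (length(mode) == 1L && grepl("^x_linked", mode)) {
    stop("X-linked inheritance modes are not supported: ",
         "the method phases autosomes through both parents")
  }
  mode <- match.arg(mode)
  stopifnot(start_pos <= end_pos, flank_bp >= 0)
  transmitting_parents <- match.arg(transmitting_parents,
                                    c("paternal", "maternal"),
                                    several.ok = TRUE)
  if (length(transmitting_parents) == 0L) {
    stop("transmitting_parents must be non-empty")
  }
  if (is.null(reference_carries)) {
    reference_carries <- stats::setNames(
      rep(TRUE, length(transmitting_parents)), transmitting_parents)
  }
  stopifnot(all(transmitting_parents %in% names(reference_carries)))
  structure(list(chrom = chrom,
                 start_pos = as.numeric(start_pos),
                 end_pos = as.numeric(end_pos),
                 mode = mode,
                 transmitting_parents = transmitting_parents,
                 flank_bp = as.numeric(flank_bp),
                 reference_carries = reference_carries),
            class = "disease_locus")
}

#' Call carrier status for one parental origin
#'
#' A breakpoint interval intersecting the locus interval is a
#' `recombinant_no_call`. Otherwise the block covering the locus midpoint
#' makes the call: state I means the embryo inherited the reference child's
#' haplotype, hence `carries_mutation` when the reference carries the mutation
#' on this origin (and `free_of_mutation` otherwise; reversed when
#' `reference_carries` is FALSE). Too few supporting sites in the flanked
#' window, or no covering block, is `no_call_insufficient_data`.
#'
#' @param seg A `block_segmentation` for this embryo and origin.
#' @param locus A [disease_locus()].
#' @param origin `"paternal"` or `"maternal"`.
#' @param params [hmm_parameters()] (supplies `min_block_sites`).
#' @return List with `call`, `state_at_locus`, `mean_posterior`,
#'   `n_sites_window`.
#' @export
call_origin_status <- function(seg, locus, origin, params = hmm_parameters()) {
  no_call <- list(call = "no_call_insufficient_data",
                  state_at_locus = NA_character_,
                  mean_posterior = NA_real_,
                  n_sites_window = 0L)
  blocks <- seg$blocks[seg$blocks$chrom == locus$chrom, , drop = FALSE]
  if (nrow(blocks) == 0L) {
    warning("no haplotype blocks on ", locus$chrom, " for ",
            attr(seg, "embryo_id"), "/", origin)
    return(no_call)
  }
  w_lo <- locus$start_pos - locus$flank_bp
  w_hi <- locus$end_pos + locus$flank_bp
  sites <- seg$sites[seg$sites$chrom == locus$chrom, , drop = FALSE]
  in_window <- sites$pos >= w_lo & sites$pos <= w_hi & !is.na(sites$obs)

  bp <- seg$breakpoints[seg$breakpoints$chrom == locus$chrom, , drop = FALSE]
  recomb <- nrow(bp) > 0L &&
    any(bp$left_pos < locus$end_pos & bp$right_pos > locus$start_pos)
  if (recomb) {
    return(list(call = "recombinant_no_call",
                state_at_locus = NA_character_,
                mean_posterior = NA_real_,
                n_sites_window = sum(in_window)))
  }

  mid <- floor((locus$start_pos + locus$end_pos) / 2)
  cover <- which(blocks$start_pos <= mid & blocks$end_pos >= mid)
  if (length(cover) == 0L) return(no_call)
  blk <- blocks[cover[1], ]

  in_block <- in_window & sites$pos >= blk$start_pos & sites$pos <= blk$end_pos
  n_support <- sum(in_block)
  if (n_support < params$min_block_sites) {
    return(list(call = "no_call_insufficient_data",
                state_at_locus = blk$state,
                mean_posterior = NA_real_,
                n_sites_window = n_support))
  }
  all_window <- sites$pos >= w_lo & sites$pos <= w_hi
  post_I <- sites$posterior_I[all_window]
  mean_post <- if (blk$state == "I") mean(post_I) else mean(1 - post_I)

  carries <- locus$reference_carries[[origin]]
  call <- if ((blk$state == "I") == isTRUE(carries)) {
    "carries_mutation"
  } else {
    "free_of_mutation"
  }
  list(call = call, state_at_locus = blk$state,
       mean_posterior = mean_post, n_sites_window = n_support)
}

#' Combine per-origin calls into an overall status
#'
#' Dominant: carrying the transmitting origin's mutation is `affected`, being
#' free of it is `unaffected`. Recessive with both parents transmitting: both
#' origins carried is `affected`, exactly one is `carrier`, neither is
#' `unaffected`. Any per-origin no-call makes the overall status `no_call`.
#'
#' @param calls Named character vector/list of per-origin calls (names are the
#'   transmitting origins).
#' @param mode Inheritance mode of the locus.
#' @return `"affected"`, `"carrier"`, `"unaffected"` or `"no_call"`.
#' @export
combine_calls <- function(calls,
                          mode = c("autosomal_dominant",
                                   "autosomal_recessive")) {
  mode <- match.arg(mode)
  calls <- unlist(calls)
  stopifnot(all(calls %in% ORIGIN_CALLS))
  if (any(calls %in% c("recombinant_no_call", "no_call_insufficient_data"))) {
    return("no_call")
  }
  n_carry <- sum(calls == "carries_mutation")
  if (mode == "autosomal_dominant") {
    if (n_carry > 0) "affected" else "unaffected"
  } else {
    if (n_carry == length(calls)) {
      "affected"
    } else if (n_carry > 0) {
      "carrier"
    } else {
      "unaffected"
    }
  }
}

#' Diagnose one embryo from its block segmentations
#'
#' @param segs Named list of `block_segmentation` per origin for this embryo
#'   (names `"paternal"`/`"maternal"`, covering `locus$transmitting_parents`).
#' @param locus A [disease_locus()].
#' @param params [hmm_parameters()].
#' @return A `diagnosis_report` list: `embryo_id`, `origins` (per-origin call
#'   detail), `overall_status`.
#' @export
diagnose_embryo <- function(segs, locus, params = hmm_parameters()) {
  origins <- lapply(stats::setNames(nm = locus$transmitting_parents),
                    function(or) {
                      if (is.null(segs[[or]])) {
                        list(call = "no_call_insufficient_data",
                             state_at_locus = NA_character_,
                             mean_posterior = NA_real_,
                             n_sites_window = 0L)
                      } else {
                        call_origin_status(segs[[or]], locus, or, params)
                      }
                    })
  ids <- vapply(segs, function(s) attr(s, "embryo_id"), character(1))
  structure(list(embryo_id = unique(ids)[1],
                 origins = origins,
                 overall_status = combine_calls(
                   vapply(origins, `[[`, character(1), "call"), locus$mode)),
            class = "diagnosis_report")
}

#' Summarize a family of diagnosis reports
#'
#' @param reports List of `diagnosis_report` objects.
#' @return List with `n_embryos`, `status_counts` (named counts over overall
#'   statuses), `origin_call_counts` (per origin), and `embryos` (per-embryo
#'   detail, ordered by embryo id). Serializes directly to JSON.
#' @export
summarize_family <- function(reports) {
  stopifnot(length(reports) >= 1)
  ids <- vapply(reports, `[[`, character(1), "embryo_id")
  reports <- reports[order(ids)]
  ids <- sort(ids)
  statuses <- vapply(reports, `[[`, character(1), "overall_status")
  status_counts <- as.list(table(factor(
    statuses, levels = c("affected", "carrier", "unaffected", "no_call"))))
  status_counts <- lapply(status_counts, as.integer)

  origins <- unique(unlist(lapply(reports, function(r) names(r$origins))))
  origin_call_counts <- lapply(stats::setNames(nm = origins), function(or) {
    calls <- vapply(reports, function(r) {
      if (is.null(r$origins[[or]])) NA_character_ else r$origins[[or]]$call
    }, character(1))
    cc <- as.list(table(factor(calls, levels = ORIGIN_CALLS)))
    lapply(cc, as.integer)
  })

  detail <- lapply(reports, function(r) {
    list(embryo_id = r$embryo_id,
         overall_status = r$overall_status,
         origins = lapply(r$origins, function(o) {
           list(call = o$call,
                state_at_locus = o$state_at_locus,
                mean_posterior = o$mean_posterior,
                n_sites_window = o$n_sites_window)
         }))
  })
  list(n_embryos = length(reports),
       status_counts = status_counts,
       origin_call_counts = origin_call_counts,
       embryos = detail)
}

#' Write a diagnosis summary as JSON
#' @param summary Output of [summarize_family()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnosis_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 10, na = "null")
  invisible(path)
}
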
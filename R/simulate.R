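# Synthetic family generator with known ground truth.
#
# Emulates the clinical input: bulk-DNA parents and reference child (clean
# genotypes) plus WGA-amplified embryo blastomeres whose genotypes carry
# allelic drop-out (ADO), allele replication errors and missing calls.
# Haplotypes are stored as alt-allele dosage vectors (0/1) per parental
# haplotype; meioses copy one haplotype, switching at crossover positions.

#' Simulation configuration
#'
#' @param n_sites SNP sites on the chromosome. Default 6000 on 90 Mb
#'   (~1 site / 15 kb, array-like density).
#' @param chrom Chromosome label. Default `"chr16"`.
#' @param chrom_length_bp Chromosome length. Default 90 Mb.
#' @param het_father,het_mother Per-site heterozygosity of each parent
#'   (independent). Default 0.5 each, so each origin is informative at an
#'   expected 25% of sites.
#' @param n_embryos Number of embryos. Default 4.
#' @param crossover_mean Mean crossovers per meiosis (Poisson), i.e. the
#'   genetic length in Morgans. Default 1.0.
#' @param max_crossovers Upper truncation of the Poisson crossover count
#'   (resampled). Default `Inf` (no truncation).
#' @param fixed_meioses Optional fully deterministic meioses: a list with
#'   elements `reference` and `embryos`; `reference` is
#'   `list(paternal = list(start_hap =, breakpoints =), maternal = ...)`,
#'   `embryos` a list of the same shape, one per embryo. When supplied, these
#'   replace random meioses.
#' @param p_ado Per-heterozygous-site allelic drop-out probability in embryos.
#'   Default 0.15, typical of single-cell WGA.
#' @param p_err Per-allele replication error (flip) probability. Default 0.01.
#' @param p_missing Per-genotype missing probability (stands in for
#'   non-uniform coverage). Default 0.02.
#' @param locus Optional [disease_locus()] carried through to truth tables.
#' @param mutation_haplotype Named integer (`paternal`, `maternal`): which
#'   parental haplotype (1 or 2) carries the mutation. Default both 1.
#' @param sample_ids Named list: `father`, `mother`, `reference_child`,
#'   `embryos` (character vector of length `n_embryos`).
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_sites = 6000,
                              chrom = "chr16",
                              chrom_length_bp = 90e6,
                              het_father = 0.5,
                              het_mother = 0.5,
                              n_embryos = 4,
                              crossover_mean = 1.0,
                              max_crossovers = Inf,
                              fixed_meioses = NULL,
                              p_ado = 0.15,
                              p_err = 0.01,
                              p_missing = 0.02,
                              locus = NULL,
                              mutation_haplotype = c(paternal = 1L,
                                                     maternal = 1L),
                              sample_ids = NULL,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for reproducible simulation")
  }
  stopifnot(n_sites >= 1, chrom_length_bp > n_sites,
            het_father >= 0, het_father <= 1,
            het_mother >= 0, het_mother <= 1,
            n_embryos >= 1, crossover_mean >= 0,
            p_ado >= 0, p_ado <= 1, p_err >= 0, p_err <= 1,
            p_missing >= 0, p_missing <= 1,
            all(mutation_haplotype %in% 1:2))
  if (is.null(sample_ids)) {
    sample_ids <- list(father = "F1", mother = "M1", reference_child = "C1",
                       embryos = paste0("E", seq_len(n_embryos)))
  }
  stopifnot(length(sample_ids$embryos) == n_embryos)
  structure(list(n_sites = as.integer(n_sites), chrom = chrom,
                 chrom_length_bp = chrom_length_bp,
                 het_father = het_father, het_mother = het_mother,
                 n_embryos = as.integer(n_embryos),
                 crossover_mean = crossover_mean,
                 max_crossovers = max_crossovers,
                 fixed_meioses = fixed_meioses,
                 p_ado = p_ado, p_err = p_err, p_missing = p_missing,
                 locus = locus, mutation_haplotype = mutation_haplotype,
                 sample_ids = sample_ids, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate phased parental haplotypes and the site scaffold
#'
#' Draws sorted unique site positions uniformly on the chromosome, random
#' ref/alt bases, and per-parent phased haplotypes: heterozygous sites get one
#' ref and one alt allele in random order, homozygous sites both copies of a
#' random allele.
#'
#' @param cfg A [simulation_config()].
#' @param seed Optional seed (defaults to the config's; pass NA to use the
#'   current RNG state).
#' @return List: `sites` data.frame and `father`/`mother` 2 x n_sites 0/1
#'   matrices (rows = haplotype 1 and 2, values = alt dosage).
#' @export
simulate_parents <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n <- cfg$n_sites
  pos <- sort(sample.int(cfg$chrom_length_bp - 1L, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  sites <- data.frame(chrom = cfg$chrom, pos = pos,
                      site_id = paste0("s", seq_len(n)),
                      ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  draw_parent <- function(het) {
    h <- matrix(0L, nrow = 2, ncol = n)
    is_het <- stats::runif(n) < het
    # het: one ref one alt, random phase
    alt_on_1 <- stats::runif(n) < 0.5
    h[1, is_het & alt_on_1] <- 1L
    h[2, is_het & !alt_on_1] <- 1L
    # hom: both alleles ref or alt with equal probability
    hom_alt <- !is_het & stats::runif(n) < 0.5
    h[, hom_alt] <- 1L
    h
  }
  list(sites = sites,
       father = draw_parent(cfg$het_father),
       mother = draw_parent(cfg$het_mother))
}

#' Simulate one meiosis
#'
#' The gamete copies one parental haplotype, starting from a random (or fixed)
#' haplotype and switching at each crossover. Crossover count is Poisson with
#' mean `crossover_mean` (optionally truncated), positions uniform on the
#' chromosome; or a fixed specification `list(start_hap, breakpoints)`.
#'
#' @param hap 2 x n_sites parental haplotype matrix.
#' @param pos Site positions.
#' @param cfg A [simulation_config()].
#' @param fixed Optional `list(start_hap =, breakpoints =)`.
#' @param seed Optional seed (default: current RNG state).
#' @return List: `gamete` (alt-dosage vector), `hap_index` (1/2 per site),
#'   `crossovers` (positions), `start_hap`.
#' @export
simulate_meiosis <- function(hap, pos, cfg, fixed = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(fixed)) {
    start_hap <- as.integer(fixed$start_hap)
    xo <- sort(as.numeric(fixed$breakpoints))
  } else {
    start_hap <- sample(1:2, 1)
    k <- stats::rpois(1, cfg$crossover_mean)
    while (k > cfg$max_crossovers) k <- stats::rpois(1, cfg$crossover_mean)
    xo <- sort(stats::runif(k, min = 1, max = cfg$chrom_length_bp))
  }
  # haplotype index per site: parity of crossovers to the left
  n_left <- findInterval(pos, xo)
  hap_index <- ifelse(n_left %% 2 == 0, start_hap, 3L - start_hap)
  gamete <- hap[cbind(hap_index, seq_along(pos))]
  list(gamete = gamete, hap_index = hap_index, crossovers = xo,
       start_hap = start_hap)
}

#' Apply WGA artifacts to a diploid genotype track
#'
#' Per heterozygous site, with probability `p_ado` one random allele drops out
#' (the genotype becomes homozygous for the survivor). Independently, each
#' resulting allele copy flips with probability `p_err`. Finally the genotype
#' is set missing with probability `p_missing`. Every event is recorded.
#'
#' @param pat_allele,mat_allele 0/1 alt-dosage vectors of the true transmitted
#'   alleles.
#' @param cfg A [simulation_config()].
#' @param seed Optional seed (default: current RNG state).
#' @return List: `gt` (observed dosage codes with NA for missing) and
#'   `log` data.frame(site, event).
#' @export
apply_wga_artifacts <- function(pat_allele, mat_allele, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(pat_allele)
  a1 <- pat_allele
  a2 <- mat_allele
  events <- list()

  het <- a1 != a2
  ado <- het & stats::runif(n) < cfg$p_ado
  if (any(ado)) {
    keep_first <- stats::runif(n) < 0.5
    surv <- ifelse(keep_first, a1, a2)
    a1[ado] <- surv[ado]
    a2[ado] <- surv[ado]
    events$ado <- data.frame(site = which(ado), event = "ado")
  }
  flip1 <- stats::runif(n) < cfg$p_err
  flip2 <- stats::runif(n) < cfg$p_err
  a1[flip1] <- 1L - a1[flip1]
  a2[flip2] <- 1L - a2[flip2]
  if (any(flip1 | flip2)) {
    events$err <- data.frame(site = which(flip1 | flip2), event = "error")
  }
  gt <- a1 + a2
  miss <- stats::runif(n) < cfg$p_missing
  gt[miss] <- NA_integer_
  if (any(miss)) {
    events$missing <- data.frame(site = which(miss), event = "missing")
  }
  log <- if (length(events)) do.call(rbind, unname(events)) else
    data.frame(site = integer(0), event = character(0))
  rownames(log) <- NULL
  list(gt = gt, log = log)
}

hap_at <- function(start_hap, crossovers, position) {
  n_left <- sum(crossovers < position)
  if (n_left %% 2 == 0) start_hap else 3L - start_hap
}

#' Simulate a whole family in memory
#'
#' Parents, an artifact-free reference child, and `n_embryos` embryos with WGA
#' artifacts, plus the full truth table.
#'
#' @param cfg A [simulation_config()]. The config seed drives all randomness.
#' @return A `sim_family` list: `cfg`, `sites`, `parents`, `gm` (observed
#'   `genotype_matrix`), `role_map`, `truth` (per-embryo hap indices, IBD
#'   indicators, crossovers, carrier status), `artifact_logs`.
#' @export
simulate_family <- function(cfg) {
  set.seed(cfg$seed)
  par <- simulate_parents(cfg, seed = NA)
  sites <- par$sites
  pos <- sites$pos
  fx <- cfg$fixed_meioses

  ref_pat <- simulate_meiosis(par$father, pos, cfg,
                              fixed = fx$reference$paternal)
  ref_mat <- simulate_meiosis(par$mother, pos, cfg,
                              fixed = fx$reference$maternal)

  embryos <- vector("list", cfg$n_embryos)
  artifact_logs <- vector("list", cfg$n_embryos)
  names(embryos) <- names(artifact_logs) <- cfg$sample_ids$embryos
  for (e in seq_len(cfg$n_embryos)) {
    fe <- fx$embryos[[e]]
    epat <- simulate_meiosis(par$father, pos, cfg, fixed = fe$paternal)
    emat <- simulate_meiosis(par$mother, pos, cfg, fixed = fe$maternal)
    wga <- apply_wga_artifacts(epat$gamete, emat$gamete, cfg)
    embryos[[e]] <- list(paternal = epat, maternal = emat,
                         true_gt = epat$gamete + emat$gamete,
                         obs_gt = wga$gt)
    artifact_logs[[e]] <- wga$log
  }

  ids <- cfg$sample_ids
  role_map <- stats::setNames(
    c("father", "mother", "reference_child", rep("embryo", cfg$n_embryos)),
    c(ids$father, ids$mother, ids$reference_child, ids$embryos))
  gt <- cbind(colSums(par$father), colSums(par$mother),
              ref_pat$gamete + ref_mat$gamete)
  for (e in seq_len(cfg$n_embryos)) gt <- cbind(gt, embryos[[e]]$obs_gt)
  storage.mode(gt) <- "integer"
  samples <- data.frame(sample_id = names(role_map),
                        role = unname(role_map), stringsAsFactors = FALSE)
  gm <- new_genotype_matrix(sites, samples, gt)

  # truth: per embryo x origin hap indices, IBD-with-reference, crossovers,
  # carrier status at the locus
  truth_haps <- list(reference = list(paternal = ref_pat, maternal = ref_mat))
  ibd <- lapply(embryos, function(em) {
    list(paternal = em$paternal$hap_index == ref_pat$hap_index,
         maternal = em$maternal$hap_index == ref_mat$hap_index)
  })
  carriers <- NULL
  if (!is.null(cfg$locus)) {
    mid <- floor((cfg$locus$start_pos + cfg$locus$end_pos) / 2)
    ref_gam <- list(paternal = ref_pat, maternal = ref_mat)
    carriers <- do.call(rbind, lapply(names(embryos), function(id) {
      em <- embryos[[id]]
      do.call(rbind, lapply(c("paternal", "maternal"), function(or) {
        g <- em[[or]]
        xo_all <- c(g$crossovers, ref_gam[[or]]$crossovers)
        data.frame(
          embryo_id = id, origin = or,
          carries = hap_at(g$start_hap, g$crossovers, mid) ==
            unname(cfg$mutation_haplotype[[or]]),
          recombinant_in_locus = any(xo_all >= cfg$locus$start_pos &
                                       xo_all <= cfg$locus$end_pos),
          stringsAsFactors = FALSE)
      }))
    }))
    rownames(carriers) <- NULL
  }

  structure(list(cfg = cfg, sites = sites, parents = par,
                 reference = list(paternal = ref_pat, maternal = ref_mat),
                 embryos = embryos, gm = gm, role_map = role_map,
                 ibd = ibd, carriers = carriers,
                 artifact_logs = artifact_logs),
            class = "sim_family")
}

gt_to_vcf <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

#' Write a simulated family to disk
#'
#' Emits a multi-sample VCF 4.2 (father, mother, reference child, embryos)
#' plus plain-text truth tables.
#'
#' @param cfg A [simulation_config()] (or a `sim_family` from
#'   [simulate_family()] to avoid re-simulating).
#' @param dir Output directory (created if absent).
#' @return The `sim_family`, with `paths` added (vcf, truth tables), invisibly.
#' @export
emit_family <- function(cfg, dir) {
  fam <- if (inherits(cfg, "sim_family")) cfg else simulate_family(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- fam$cfg

  vcf_path <- file.path(dir, "family.vcf")
  con <- file(vcf_path, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=embryohap-simulator",
    sprintf("##contig=<ID=%s,length=%d>", cfg$chrom,
            as.integer(cfg$chrom_length_bp)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(fam$role_map)), collapse = "\t")), con)
  gt_cols <- apply(fam$gm$gt, 2, gt_to_vcf)
  body <- cbind(fam$sites$chrom, fam$sites$pos, fam$sites$site_id,
                fam$sites$ref, fam$sites$alt, ".", "PASS", ".", "GT", gt_cols)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  close(con)

  # truth tables
  hap_tbl <- data.frame(chrom = fam$sites$chrom, pos = fam$sites$pos,
                        stringsAsFactors = FALSE)
  hap_tbl$reference.paternal.hap <- fam$reference$paternal$hap_index
  hap_tbl$reference.maternal.hap <- fam$reference$maternal$hap_index
  for (id in names(fam$embryos)) {
    for (or in c("paternal", "maternal")) {
      hap_tbl[[paste0(id, ".", or, ".hap")]] <-
        fam$embryos[[id]][[or]]$hap_index
      hap_tbl[[paste0(id, ".", or, ".ibd")]] <-
        as.integer(fam$ibd[[id]][[or]])
    }
  }
  hap_path <- file.path(dir, "truth_haplotypes.tsv")
  write_tsv(hap_tbl, hap_path)

  xo_rows <- list()
  add_xo <- function(sample, origin, xo) {
    if (length(xo) == 0) return()
    xo_rows[[length(xo_rows) + 1L]] <<- data.frame(
      sample = sample, origin = origin, position = round(xo),
      stringsAsFactors = FALSE)
  }
  add_xo("reference", "paternal", fam$reference$paternal$crossovers)
  add_xo("reference", "maternal", fam$reference$maternal$crossovers)
  for (id in names(fam$embryos)) {
    add_xo(id, "paternal", fam$embryos[[id]]$paternal$crossovers)
    add_xo(id, "maternal", fam$embryos[[id]]$maternal$crossovers)
  }
  xo_tbl <- if (length(xo_rows)) do.call(rbind, xo_rows) else
    data.frame(sample = character(0), origin = character(0),
               position = numeric(0))
  xo_path <- file.path(dir, "truth_crossovers.tsv")
  write_tsv(xo_tbl, xo_path)

  paths <- list(vcf = vcf_path, truth_haplotypes = hap_path,
                truth_crossovers = xo_path)
  if (!is.null(fam$carriers)) {
    car_path <- file.path(dir, "truth_carriers.tsv")
    write_tsv(fam$carriers, car_path)
    paths$truth_carriers <- car_path
  }
  fam$paths <- paths
  invisible(fam)
}
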
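#' Configuration for the founder-mosaic panel simulator
#'
#' The generator draws, per subpopulation, `founders` founder haplotypes
#' from shared founder allele frequencies, then builds each line as a
#' mosaic of founder segments: crossover breakpoints follow a Poisson
#' process with rate `generations` per Morgan along each linkage group and
#' the founder identity is resampled at every breakpoint. Fewer founders
#' mean higher within-group relatedness and longer-range LD; more
#' generations mean faster LD decay with map distance. Divergence regions
#' shift the founder frequencies of the second subpopulation by `delta_p`
#' inside the stated interval.
#'
#' @param n_lines integer length-2: lines per subpopulation
#'   (group 1 labelled `"winter"`, group 2 `"spring"`).
#' @param groups data frame `chrom`, `length_cm`, `n_markers` describing
#'   the genetic map to simulate.
#' @param founders integer length-2: founder haplotypes per subpopulation
#'   (each >= 2). Background same-segment LD scales like `1/(F-1)`, so the
#'   defaults 8 and 4 give a broader winter-like pool (adjacent-marker r^2
#'   near 0.15) against a narrow spring-like pool (near 0.35), the
#'   relatedness contrast typical of crop growth-habit subpopulations.
#' @param generations length-2 mosaic generations per subpopulation
#'   (crossover rate per Morgan); each >= 1.
#' @param founder_freq length-2 range of the Uniform founder allele
#'   frequency distribution (avoids near-fixed markers).
#' @param regions optional data frame `chrom`, `start_cm`, `end_cm`,
#'   `delta_p` of planted divergence regions (frequency shift applied to
#'   subpopulation 2, direction chosen to stay in `[0, 1]`).
#' @param share_founders if `TRUE` (default), one founder pool of size
#'   `max(founders)` is drawn and subpopulation `g` uses its first
#'   `founders[g]` haplotypes — a narrow group nested in a broad one, as
#'   when both breeding groups trace back to common primary founders.
#'   Outside planted regions the groups then differ only by sampling, so
#'   a label-permutation null is well calibrated when the pools coincide.
#'   With `FALSE` each subpopulation draws its own founders from the same
#'   frequencies, adding genuine founder drift to every chromosome.
#' @param missing_rate fraction of calls masked at random, in `[0, 1)`.
#'   Default 0.02, typical of DArT panels.
#' @param seed integer seed making the draw reproducible.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = c(50, 50),
                       groups = data.frame(
                         chrom = c("1A", "1B", "1R"),
                         length_cm = 100, n_markers = 120),
                       founders = c(8, 4), generations = c(8, 8),
                       founder_freq = c(0.1, 0.9), regions = NULL,
                       share_founders = TRUE, missing_rate = 0.02,
                       seed = 1) {
  if (length(generations) == 1) generations <- rep(generations, 2)
  if (length(founders) == 1) founders <- rep(founders, 2)
  stopifnot(length(n_lines) == 2, all(n_lines >= 1),
            all(c("chrom", "length_cm", "n_markers") %in% names(groups)),
            all(groups$n_markers >= 1), all(groups$length_cm > 0),
            length(founders) == 2, all(founders >= 2),
            length(generations) == 2, all(generations >= 1),
            length(founder_freq) == 2,
            founder_freq[1] >= 0, founder_freq[2] <= 1,
            founder_freq[1] <= founder_freq[2],
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(regions))
    stopifnot(all(c("chrom", "start_cm", "end_cm", "delta_p") %in%
                    names(regions)),
              all(regions$chrom %in% groups$chrom),
              all(regions$delta_p >= 0 & regions$delta_p <= 1))
  structure(list(n_lines = as.integer(n_lines), groups = groups,
                 founders = as.integer(founders),
                 generations = as.numeric(generations),
                 founder_freq = founder_freq, regions = regions,
                 share_founders = isTRUE(share_founders),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Paper-scale preset configuration
#'
#' A realistic-scale panel mirroring a worldwide triticale collection: 22
#' linkage groups (7 A, 7 B; 1R-7R with 2R split in two), 2,079 markers
#' distributed 306 / 502 / 1,271 over the A / B / R genomes, and 74 + 81
#' lines in the two growth-habit subpopulations.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
paper_preset <- function(seed = 1, ...) {
  split_counts <- function(total, k) {
    base <- total %/% k
    n <- rep.int(as.integer(base), k)
    n[seq_len(total - base * k)] <- as.integer(base + 1)
    n
  }
  chroms <- c(paste0(1:7, "A"), paste0(1:7, "B"),
              "1R", "2R-1", "2R-2", paste0(3:7, "R"))
  lens <- c(rep(100, 14), 100, 50, 50, rep(100, 5))
  nm <- c(split_counts(306, 7), split_counts(502, 7), split_counts(1271, 8))
  args <- list(n_lines = c(74, 81),
               groups = data.frame(chrom = chroms, length_cm = lens,
                                   n_markers = nm),
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' Simulate a dominant-marker panel with known ground truth
#'
#' See [sim_config()] for the generative model. The result is fully
#' reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return List: `genotypes` ([genotype_matrix()] with habit labels
#'   `winter` / `spring`), `map` ([genetic_map()]), `truth` (list with
#'   `founder_freq` — realized founder allele frequencies per
#'   subpopulation —, `expected_pic` per subpopulation, `regions`,
#'   `breakpoints`, `founder_haplotypes`, `config`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gr <- config$groups
  chrom <- rep(gr$chrom, gr$n_markers)
  pos <- unlist(lapply(seq_len(nrow(gr)), function(k)
    sort(stats::runif(gr$n_markers[k], 0, gr$length_cm[k]))))
  marker <- unlist(lapply(seq_len(nrow(gr)), function(k)
    sprintf("%s_m%03d", gr$chrom[k], seq_len(gr$n_markers[k]))))
  map <- genetic_map(marker, chrom, pos)
  M <- nrow(map)

  p_base <- stats::runif(M, config$founder_freq[1], config$founder_freq[2])
  p_grp <- cbind(p_base, p_base)
  if (!is.null(config$regions)) {
    for (r in seq_len(nrow(config$regions))) {
      rg <- config$regions[r, ]
      in_rg <- map$chrom == rg$chrom & map$pos_cm >= rg$start_cm &
        map$pos_cm <= rg$end_cm
      up_ok <- p_base[in_rg] + rg$delta_p <= 1
      dn_ok <- p_base[in_rg] - rg$delta_p >= 0
      if (any(!up_ok & !dn_ok))
        stop("infeasible delta_p ", rg$delta_p, " in region ", r,
             ": founder frequency leaves [0, 1] in both directions")
      shift <- ifelse(up_ok, rg$delta_p, -rg$delta_p)
      p_grp[in_rg, 2] <- p_base[in_rg] + shift
    }
  }

  if (config$share_founders) {
    Fmax <- max(config$founders)
    pool <- matrix(stats::rbinom(Fmax * M, 1, rep(p_grp[, 1], each = Fmax)),
                   nrow = Fmax)
    founders <- lapply(1:2, function(g)
      pool[seq_len(config$founders[g]), , drop = FALSE])
    shifted <- which(p_grp[, 2] != p_grp[, 1])
    if (length(shifted)) {
      F2 <- config$founders[2]
      founders[[2]][, shifted] <-
        stats::rbinom(F2 * length(shifted), 1,
                      rep(p_grp[shifted, 2], each = F2))
    }
  } else {
    founders <- lapply(1:2, function(g) {
      F <- config$founders[g]
      matrix(stats::rbinom(F * M, 1, rep(p_grp[, g], each = F)), nrow = F)
    })
  }
  truth_freq <- vapply(founders, colMeans, numeric(M))

  labels <- c("winter", "spring")
  calls <- matrix(NA_integer_, sum(config$n_lines), M)
  habit <- character(sum(config$n_lines))
  line_ids <- character(sum(config$n_lines))
  bps <- vector("list", sum(config$n_lines))
  row <- 0
  for (g in 1:2) {
    F <- config$founders[g]; G <- config$generations[g]
    for (l in seq_len(config$n_lines[g])) {
      row <- row + 1
      line_ids[row] <- sprintf("%s_%03d", labels[g], l)
      habit[row] <- labels[g]
      line_bp <- list()
      for (k in seq_len(nrow(gr))) {
        L <- gr$length_cm[k]
        nb <- stats::rpois(1, G * L / 100)
        bp <- sort(stats::runif(nb, 0, L))
        fid <- sample.int(F, nb + 1, replace = TRUE)
        sel <- map$chrom == gr$chrom[k]
        seg <- findInterval(map$pos_cm[sel], bp) + 1
        calls[row, sel] <- founders[[g]][cbind(fid[seg], which(sel))]
        line_bp[[gr$chrom[k]]] <- list(breakpoints = bp, founder = fid)
      }
      bps[[row]] <- line_bp
    }
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(calls)) < config$missing_rate
    calls[mask] <- NA_integer_
  }
  dimnames(calls) <- list(line_ids, map$marker)
  gm <- genotype_matrix(calls, habit = habit)
  truth <- list(founder_freq = truth_freq,
                expected_pic = apply(truth_freq, 2, pic),
                regions = config$regions, breakpoints = bps,
                founder_haplotypes = founders, config = config)
  list(genotypes = gm, map = map, truth = truth)
}
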
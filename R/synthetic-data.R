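# Synthetic-data generation with known ground truth: founder panels,
# individual-based selection experiments with pooled sequencing, activity
# traces, and diallel phenotypes. Every input the analysis stages consume
# can be produced here with the true parameters retained.

#' Generate a panel of fully inbred founder lines
#'
#' Each site is biallelic; the number of lines carrying the alt allele is
#' \code{round(f * n_lines)} (clipped to keep the site polymorphic) where
#' f is drawn from \code{maf_spectrum}.
#'
#' @param n_lines number of inbred lines (>= 2)
#' @param n_sites_per_chrom sites per chromosome
#' @param chrom_labels chromosome names (default the five fly arms)
#' @param maf_spectrum list: \code{list(dist = "uniform", min, max)},
#'   \code{list(dist = "point", value)} or
#'   \code{list(dist = "beta", shape1, shape2)} over the alt frequency
#' @param chrom_length span in bp over which positions are placed
#' @param seed integer seed
#' @return object of class \code{founder_panel}: sites data.frame (chrom,
#'   pos, ref, alt), geno matrix lines x sites (0 = ref, 1 = alt)
#' @export
generate_founder_panel <- function(n_lines = 10, n_sites_per_chrom = 100,
                                   chrom_labels = c("2L", "2R", "3L", "3R", "X"),
                                   maf_spectrum = list(dist = "uniform",
                                                       min = 0.05, max = 0.5),
                                   chrom_length = 2e7, seed = NULL) {
  stopifnot(n_lines >= 2, n_sites_per_chrom >= 1)
  draw_f <- switch(maf_spectrum$dist %||% "uniform",
    uniform = function(n) runif(n, maf_spectrum$min, maf_spectrum$max),
    point = function(n) rep(maf_spectrum$value, n),
    beta = function(n) rbeta(n, maf_spectrum$shape1, maf_spectrum$shape2),
    stop_config("unknown maf_spectrum dist '%s'", maf_spectrum$dist))
  if (identical(maf_spectrum$dist, "uniform") &&
      (maf_spectrum$min < 0 || maf_spectrum$max > 1 ||
       maf_spectrum$min > maf_spectrum$max))
    stop_config("invalid uniform spectrum parameters")
  with_seed(seed, {
    n_sites <- n_sites_per_chrom * length(chrom_labels)
    sites <- data.frame(
      chrom = rep(chrom_labels, each = n_sites_per_chrom),
      pos = as.integer(replicate(length(chrom_labels),
        sort(sample.int(chrom_length, n_sites_per_chrom)))),
      ref = "A", alt = "T", stringsAsFactors = FALSE)
    f <- draw_f(n_sites)
    k <- pmin(pmax(round(f * n_lines), 1L), n_lines - 1L)
    geno <- matrix(0L, n_lines, n_sites)
    for (s in seq_len(n_sites)) geno[sample.int(n_lines, k[s]), s] <- 1L
    structure(list(sites = sites, geno = geno, n_lines = n_lines),
              class = "founder_panel")
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", x$n_lines, "lines x", nrow(x$sites), "sites\n")
  invisible(x)
}

#' Experiment configuration for the selection simulator
#'
#' Defaults replay the selection design: 13 generations, 100 measured
#' flies per sex per population, truncation of the most extreme 25% per
#' sex, two long, two short and two control populations, 21 random-mating
#' burn-in generations at census 800, and pooled sequencing of both sex
#' pools at generations 0, 1, 2, 5, 8, 10 and 12.
#'
#' @param n_generations selection generations
#' @param n_measured_per_sex flies phenotyped per sex per generation
#' @param selection_fraction proportion chosen as parents, in (0, 1]
#' @param schemes named counts of replicate populations
#' @param qtl_effects per-site additive effect on night sleep (minutes per
#'   alt allele); zero elsewhere
#' @param env_sd environmental standard deviation (minutes)
#' @param trait_mean baseline night sleep (minutes)
#' @param sex_effect additive male effect (minutes)
#' @param clamp_trait clamp phenotypes into [0, 720] (night-sleep bounds);
#'   off by default so the additive model stays exactly linear
#' @param coverage_mean mean pooled read depth (Poisson, truncated at 1)
#' @param sequenced_generations generations sequenced
#' @param burnin_generations random-mating generations building the
#'   outbred pool
#' @param burnin_census pool size during burn-in
#' @param recomb_frac recombination fraction between adjacent sites on a
#'   chromosome (0.5 = free recombination)
#' @param seed master seed; all sub-streams derive from it
#' @return validated list of class \code{experiment_config}
#' @export
experiment_config <- function(n_generations = 13, n_measured_per_sex = 100,
                              selection_fraction = 0.25,
                              schemes = c(long = 2, short = 2, control = 2),
                              qtl_effects = NULL, env_sd = 100,
                              trait_mean = 480, sex_effect = 0,
                              clamp_trait = FALSE, coverage_mean = 100,
                              sequenced_generations = c(0, 1, 2, 5, 8, 10, 12),
                              burnin_generations = 21, burnin_census = 800,
                              recomb_frac = 0.5, seed = 1L) {
  if (selection_fraction <= 0 || selection_fraction > 1)
    stop_config("selection_fraction must be in (0, 1]")
  if (coverage_mean <= 0) stop_config("coverage_mean must be positive")
  n_parents <- floor(selection_fraction * n_measured_per_sex)
  if (n_parents < 1)
    stop_config("census too small for requested parent count")
  structure(list(
    n_generations = n_generations, n_measured_per_sex = n_measured_per_sex,
    selection_fraction = selection_fraction, schemes = schemes,
    qtl_effects = qtl_effects, env_sd = env_sd, trait_mean = trait_mean,
    sex_effect = sex_effect, clamp_trait = clamp_trait,
    coverage_mean = coverage_mean,
    sequenced_generations = sequenced_generations,
    burnin_generations = burnin_generations, burnin_census = burnin_census,
    recomb_frac = recomb_frac, seed = seed), class = "experiment_config")
}

# ---- individual-based machinery -------------------------------------------

# population: list(H1, H2 integer matrices (ind x sites), sex integer
# (0 = female, 1 = male)); males are hemizygous at X sites (H2 ignored)

switch_prob_of <- function(sites, recomb_frac) {
  sp <- rep(recomb_frac, nrow(sites))
  sp[!duplicated(sites$chrom)] <- 0.5
  sp
}

# pure-R reference implementation of the gamete kernel (oracle for tests)
make_gametes_r <- function(H1, H2, parent_idx, switch_prob, x_site,
                           parent_male) {
  S <- ncol(H1)
  out <- matrix(0L, length(parent_idx), S)
  for (i in seq_along(parent_idx)) {
    p <- parent_idx[i]
    state <- if (runif(1) < 0.5) 0L else 1L
    for (s in seq_len(S)) {
      if (s > 1 && runif(1) < switch_prob[s]) state <- 1L - state
      out[i, s] <- if (parent_male[i] && x_site[s]) H1[p, s]
                   else if (state == 0L) H1[p, s] else H2[p, s]
    }
  }
  out
}

breed <- function(pop, mothers, fathers, n_female, n_male, switch_prob,
                  x_site, use_cpp = TRUE) {
  n_off <- n_female + n_male
  mk <- if (use_cpp) .make_gametes else make_gametes_r
  mo <- sample(mothers, n_off, replace = TRUE)
  fa <- sample(fathers, n_off, replace = TRUE)
  H1 <- mk(pop$H1, pop$H2, mo, switch_prob, x_site, rep(FALSE, n_off))
  H2 <- mk(pop$H1, pop$H2, fa, switch_prob, x_site, rep(TRUE, n_off))
  list(H1 = H1, H2 = H2,
       sex = c(rep(0L, n_female), rep(1L, n_male)))
}

# allele (alt) frequency accounting for male hemizygosity at X sites
pop_freq <- function(pop, x_site, subset = seq_along(pop$sex)) {
  H1 <- pop$H1[subset, , drop = FALSE]
  H2 <- pop$H2[subset, , drop = FALSE]
  male <- pop$sex[subset] == 1L
  c1 <- colSums(H1)
  c2 <- colSums(H2)
  c2x <- colSums(H2[!male, , drop = FALSE])
  copies <- ifelse(x_site, 2 * sum(!male) + sum(male), 2 * length(subset))
  (c1 + ifelse(x_site, c2x, c2)) / copies
}

phenotype_of <- function(pop, x_site, effects, cfg) {
  qtl <- which(effects != 0)
  if (length(qtl) == 0) {
    g <- numeric(length(pop$sex))
  } else {
    male <- pop$sex == 1L
    dose <- pop$H1[, qtl, drop = FALSE] + pop$H2[, qtl, drop = FALSE]
    # males carry a single X dose
    if (any(x_site[qtl])) {
      xq <- which(x_site[qtl])
      dose[male, xq] <- pop$H1[male, qtl[xq], drop = FALSE]
    }
    g <- as.numeric(dose %*% effects[qtl])
  }
  y <- cfg$trait_mean + g + cfg$sex_effect * (pop$sex == 1L) +
    rnorm(length(g), 0, cfg$env_sd)
  if (cfg$clamp_trait) y <- pmin(pmax(y, 0), 720)
  y
}

#' Binomial pooled-sequencing read sampler
#'
#' @param true_freq allele frequency in the pool (vectorised)
#' @param coverage read depth per site (vectorised)
#' @param seed optional seed
#' @return list(ref_count, alt_count)
#' @export
sample_pool_reads <- function(true_freq, coverage, seed = NULL) {
  stopifnot(all(true_freq >= 0 & true_freq <= 1), all(coverage >= 0))
  with_seed(seed, {
    n <- max(length(true_freq), length(coverage))
    alt <- rbinom(n, coverage, true_freq)
    list(ref_count = coverage - alt, alt_count = alt)
  })
}

#' Simulate the full selection experiment
#'
#' Builds the outbred pool from the founder panel by random mating, founds
#' the replicate populations, applies per-sex truncation selection for
#' \code{n_generations}, and pools-and-sequences each population's sex
#' cohorts at the sequenced generations. The phenotype model is additive
#' (per-site effects, hemizygous X dosage in males) plus a sex effect and
#' Normal environmental noise.
#'
#' @param panel a \code{founder_panel}
#' @param config an \code{experiment_config}
#' @param use_cpp use the compiled gamete kernel (default TRUE)
#' @return list of class \code{sim_experiment}: \code{panel} (an
#'   \code{allele_count_panel} of pooled reads), \code{trajectory}
#'   (data.frame population, scheme, replicate, generation, site,
#'   true_freq of the alt allele), \code{phenotypes} (data.frame
#'   population, scheme, replicate, generation, sex, value), and
#'   \code{config}
#' @export
simulate_experiment <- function(panel, config, use_cpp = TRUE) {
  stopifnot(inherits(panel, "founder_panel"),
            inherits(config, "experiment_config"))
  cfg <- config
  effects <- cfg$qtl_effects %||% numeric(nrow(panel$sites))
  if (length(effects) != nrow(panel$sites))
    stop_config("qtl_effects must have one entry per panel site")
  x_site <- panel$sites$chrom == "X"
  sp <- switch_prob_of(panel$sites, cfg$recomb_frac)
  n_meas <- cfg$n_measured_per_sex
  n_par <- floor(cfg$selection_fraction * n_meas)

  pops <- rep(names(cfg$schemes), cfg$schemes)
  pop_ids <- unlist(lapply(seq_along(cfg$schemes), function(i)
    paste0(toupper(substr(names(cfg$schemes)[i], 1, 1)),
           seq_len(cfg$schemes[i]))))

  # burn-in: found from random founder haplotypes, then random mating
  pool <- with_seed(substream_seed(cfg$seed, "burnin"), {
    n0 <- cfg$burnin_census
    pick <- function() panel$geno[sample.int(panel$n_lines, n0,
                                             replace = TRUE), , drop = FALSE]
    pool <- list(H1 = pick(), H2 = pick(),
                 sex = rep(c(0L, 1L), length.out = n0))
    for (g in seq_len(cfg$burnin_generations)) {
      pool <- breed(pool, which(pool$sex == 0L), which(pool$sex == 1L),
                    ceiling(n0 / 2), floor(n0 / 2), sp, x_site, use_cpp)
    }
    pool
  })

  traj <- list(); phen <- list(); pool_rows <- list()
  sample_meta <- list(); ref_cols <- list(); alt_cols <- list()

  for (k in seq_along(pops)) {
    scheme <- pops[k]
    pid <- pop_ids[k]
    repl <- as.integer(sub("^[A-Z]", "", pid))
    set.seed(substream_seed(cfg$seed, paste0("pop-", pid)))

    founders_f <- sample(which(pool$sex == 0L), n_par)
    founders_m <- sample(which(pool$sex == 1L), n_par)
    cur <- breed(pool, founders_f, founders_m, n_meas, n_meas, sp, x_site,
                 use_cpp)
    for (gen in 0:cfg$n_generations) {
      y <- phenotype_of(cur, x_site, effects, cfg)
      phen[[length(phen) + 1L]] <- data.frame(
        population = pid, scheme = scheme, replicate = repl,
        generation = gen, sex = ifelse(cur$sex == 1L, "M", "F"), value = y)
      if (gen %in% cfg$sequenced_generations) {
        for (sx in c(0L, 1L)) {
          idx <- which(cur$sex == sx)
          tf <- pop_freq(cur, x_site, idx)
          cov <- pmax(1L, rpois(length(tf), cfg$coverage_mean))
          reads <- sample_pool_reads(tf, cov)
          sample_meta[[length(sample_meta) + 1L]] <- data.frame(
            population = pid, scheme = scheme, replicate = repl,
            sex = ifelse(sx == 1L, "M", "F"), generation = gen)
          ref_cols[[length(ref_cols) + 1L]] <- reads$ref_count
          alt_cols[[length(alt_cols) + 1L]] <- reads$alt_count
        }
        traj[[length(traj) + 1L]] <- data.frame(
          population = pid, scheme = scheme, replicate = repl,
          generation = gen, site = seq_len(nrow(panel$sites)),
          true_freq = pop_freq(cur, x_site))
      }
      if (gen == cfg$n_generations) break
      sel_idx <- function(sx) {
        idx <- which(cur$sex == sx)
        ord <- switch(scheme,
          long = idx[order(y[idx], decreasing = TRUE)],
          short = idx[order(y[idx])],
          control = sample(idx))
        ord[seq_len(n_par)]
      }
      cur <- breed(cur, sel_idx(0L), sel_idx(1L), n_meas, n_meas, sp,
                   x_site, use_cpp)
    }
  }

  samples <- do.call(rbind, sample_meta)
  acp <- if (is.null(samples)) NULL else allele_count_panel(
    sites = panel$sites, samples = samples,
    ref_count = do.call(cbind, ref_cols),
    alt_count = do.call(cbind, alt_cols))
  structure(list(panel = acp,
                 trajectory = do.call(rbind, traj),
                 phenotypes = do.call(rbind, phen),
                 config = cfg),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", length(unique(x$phenotypes$population)),
      "populations,", x$config$n_generations, "generations,",
      nrow(x$panel$sites), "sites\n")
  invisible(x)
}

# ---- activity traces -------------------------------------------------------

#' Simulate an activity trace with controlled sleep-bout structure
#'
#' Builds one 24-h day (repeated \code{n_days} times) in which the night
#' and day sleep totals are drawn around the requested means, partitioned
#' into the requested number of bouts (each >= 5 minutes), and placed at
#' random within the phase with waking gaps. Waking minutes carry Poisson
#' activity (shifted by 1 so a waking minute is never immobile); transient
#' pauses of 1-4 immobile minutes are inserted into waking stretches.
#'
#' @param mean_night_sleep,mean_day_sleep target minutes per phase
#' @param sd_sleep between-fly SD of realized totals (default 30)
#' @param n_night_bouts,n_day_bouts bouts per phase
#' @param n_pauses transient pauses inserted per phase
#' @param activity_rate Poisson rate of waking activity counts minus 1
#' @param n_days days recorded
#' @param lights_on_minute passed to \code{\link{activity_trace}}
#' @param id fly id
#' @param seed integer seed
#' @return an \code{activity_trace}
#' @export
simulate_activity <- function(mean_night_sleep = 400, mean_day_sleep = 200,
                              sd_sleep = 30, n_night_bouts = 4,
                              n_day_bouts = 4, n_pauses = 2,
                              activity_rate = 1.5, n_days = 1,
                              lights_on_minute = 1L, id = "fly",
                              seed = NULL) {
  check_phase <- function(total, bouts) {
    if (total < 0 || total > 720)
      stop_config("requested phase sleep outside [0, 720]")
    if (total > 0 && bouts < 1) stop_config("need >= 1 bout for sleep > 0")
    if (total + max(bouts - 1, 0) > 720)
      stop_config("requested sleep infeasible in phase")
  }
  check_phase(mean_night_sleep, n_night_bouts)
  check_phase(mean_day_sleep, n_day_bouts)
  with_seed(seed, {
    build_phase <- function(target, n_bouts, n_pauses) {
      mins <- rep(1, 720)  # start fully active; 1 = placeholder wake
      total <- if (target <= 0) 0 else
        round(min(max(rnorm(1, target, sd_sleep), 0), 720))
      nb <- if (total == 0) 0 else max(1L, min(n_bouts, total %/% SLEEP_MIN_RUN))
      if (nb > 0 && total + nb - 1 > 720) total <- 720 - nb + 1
      if (nb > 0) {
        # bout lengths: random composition of `total` into nb parts >= 5
        extra <- total - nb * SLEEP_MIN_RUN
        add <- if (extra > 0) tabulate(sample.int(nb, extra, replace = TRUE),
                                       nb) else rep(0L, nb)
        lens <- SLEEP_MIN_RUN + add
        # place bouts with >= 1 waking minute between them
        gaps_total <- 720 - total
        n_gap <- nb + 1L
        inner <- rep(1, n_gap); inner[c(1, n_gap)] <- 0
        free <- gaps_total - sum(inner)
        if (free < 0) stop_config("requested sleep infeasible in phase")
        add <- if (free > 0) tabulate(sample.int(n_gap, free, replace = TRUE),
                                      n_gap) else rep(0, n_gap)
        gaps <- inner + add
        pos <- 1
        for (bi in seq_len(nb)) {
          pos <- pos + gaps[bi]
          mins[pos:(pos + lens[bi] - 1)] <- 0
          pos <- pos + lens[bi]
        }
      }
      wake_idx <- which(mins != 0)
      mins[wake_idx] <- 1 + rpois(length(wake_idx), activity_rate)
      # insert transient pauses into interior waking runs
      if (n_pauses > 0 && length(wake_idx) > 12) {
        for (p in seq_len(n_pauses)) {
          len <- sample(1:4, 1)
          cand <- wake_idx[wake_idx > 6 & wake_idx < 720 - 6 - len]
          # only where the pause stays isolated from sleep runs
          ok <- cand[vapply(cand, function(st) {
            rng <- max(1, st - 1):min(720, st + len)
            all(mins[setdiff(rng, st:(st + len - 1))] > 0) &&
              all(mins[st:(st + len - 1)] > 0)
          }, TRUE)]
          if (length(ok)) {
            st <- sample(ok, 1)
            mins[st:(st + len - 1)] <- 0
          }
        }
      }
      mins
    }
    counts <- unlist(lapply(seq_len(n_days), function(d)
      c(build_phase(mean_day_sleep, n_day_bouts, n_pauses),
        build_phase(mean_night_sleep, n_night_bouts, n_pauses))))
    activity_trace(counts, id = id, lights_on_minute = lights_on_minute)
  })
}

# ---- diallel ---------------------------------------------------------------

#' Simulate a replicated full diallel cross
#'
#' \eqn{Y_{ijk} = \mu + g_i + g_j + s_{ij} + r_{ij} + e_{ijk}} with
#' \code{gca_true} summing to zero, symmetric \code{sca_true} and
#' antisymmetric \code{rec_true}.
#'
#' @param gca_true per-line effects (sum to zero)
#' @param sca_true symmetric matrix
#' @param rec_true antisymmetric matrix (zero diagonal)
#' @param grand_mean trait mean
#' @param noise_sd residual SD
#' @param n_per_cross replicate observations per ordered cross
#' @param seed integer seed
#' @return data.frame maternal, paternal, replicate, value
#' @export
simulate_diallel <- function(gca_true, sca_true, rec_true, grand_mean = 480,
                             noise_sd = 20, n_per_cross = 2, seed = NULL) {
  n <- length(gca_true)
  if (!all(dim(sca_true) == n) || !all(dim(rec_true) == n))
    stop_config("dimension mismatch between effect arrays")
  if (abs(sum(gca_true)) > 1e-8) stop_config("gca_true must sum to zero")
  if (max(abs(sca_true - t(sca_true))) > 1e-8)
    stop_config("sca_true must be symmetric")
  if (max(abs(rec_true + t(rec_true))) > 1e-8)
    stop_config("rec_true must be antisymmetric")
  with_seed(seed, {
    grid <- expand.grid(maternal = seq_len(n), paternal = seq_len(n),
                        replicate = seq_len(n_per_cross))
    mu_ij <- grand_mean + gca_true[grid$maternal] + gca_true[grid$paternal] +
      sca_true[cbind(grid$maternal, grid$paternal)] +
      rec_true[cbind(grid$maternal, grid$paternal)]
    grid$value <- mu_ij + rnorm(nrow(grid), 0, noise_sd)
    grid$maternal <- paste0("L", grid$maternal)
    grid$paternal <- paste0("L", grid$paternal)
    grid
  })
}
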
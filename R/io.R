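# Readers and writers for the standard text formats (PoPoolation2-style
# sync, long-format count TSV) and the end-to-end pipeline driver.

NUC <- c("A", "T", "C", "G")

#' Write an allele-count panel as sync-format text
#'
#' One row per site: chrom, pos, ref, then one colon-separated
#' A:T:C:G:N:del count column per sample. Masked cells are written as
#' zero-coverage columns.
#'
#' @param panel an \code{allele_count_panel}
#' @param path output path
#' @param header write a commented provenance header (default TRUE)
#' @return the path, invisibly
#' @export
write_sync <- function(panel, path, header = TRUE) {
  ns <- nrow(panel$sites); np <- nrow(panel$samples)
  cols <- vapply(seq_len(np), function(j) {
    counts <- matrix(0L, ns, 6L)
    ri <- match(panel$sites$ref, NUC); ai <- match(panel$sites$alt, NUC)
    rc <- panel$ref_count[, j]; ac <- panel$alt_count[, j]
    rc[is.na(rc)] <- 0L; ac[is.na(ac)] <- 0L
    counts[cbind(seq_len(ns), ri)] <- rc
    counts[cbind(seq_len(ns), ai)] <- ac
    apply(counts, 1L, paste, collapse = ":")
  }, character(ns))
  lines <- paste(panel$sites$chrom, panel$sites$pos, panel$sites$ref,
                 apply(matrix(cols, ns), 1L, paste, collapse = "\t"),
                 sep = "\t")
  if (header) {
    meta <- paste0("## sleepsweep ", as.character(utils::packageVersion("sleepsweep")),
                   " sync; samples: ",
                   paste(panel$samples$sample_id, collapse = ","))
    lines <- c(meta, lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read sync-format text into an allele-count panel
#'
#' Biallelic reduction uses the declared ref plus the single non-reference
#' nucleotide carrying reads; sites with reads on more than one
#' non-reference nucleotide are flagged multi-allelic and excluded (with a
#' message naming them). Malformed rows raise an error naming the line.
#'
#' @param path sync file
#' @param samples data.frame describing the sample columns (population,
#'   scheme, replicate, sex, generation), one row per count column
#' @param alt optional declared alt allele per site; inferred if omitted
#' @return an \code{allele_count_panel}
#' @export
read_sync <- function(path, samples, alt = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(unique(nf)) != 1)
    stop_config("ragged sync row at line %d", which(nf != nf[1L])[1L] )
  np <- nf[1L] - 3L
  if (np != nrow(samples))
    stop_config("%d count columns but %d sample rows", np, nrow(samples))
  m <- do.call(rbind, parts)
  sites <- data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
                      ref = m[, 3L], stringsAsFactors = FALSE)
  counts <- array(0L, c(nrow(m), np, 6L))
  for (j in seq_len(np)) {
    sp <- strsplit(m[, j + 3L], ":", fixed = TRUE)
    if (any(lengths(sp) != 6L))
      stop_config("malformed count field at line %d", which(lengths(sp) != 6L)[1L])
    v <- suppressWarnings(as.integer(unlist(sp)))
    if (anyNA(v)) stop_config("non-numeric counts at line %d",
                              ceiling(which(is.na(v))[1L] / 6))
    counts[, j, ] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  tot_by_nuc <- apply(counts[, , 1:4, drop = FALSE], c(1L, 3L), sum)
  ri <- match(sites$ref, NUC)
  nonref_reads <- tot_by_nuc
  nonref_reads[cbind(seq_len(nrow(m)), ri)] <- 0L
  n_nonref <- rowSums(nonref_reads > 0)
  multi <- n_nonref > 1
  if (!is.null(alt)) {
    ai <- match(alt, NUC)
  } else {
    ai <- apply(nonref_reads, 1L, which.max)
    ai[n_nonref == 0] <- ifelse(ri[n_nonref == 0] == 1L, 2L, 1L)
  }
  if (any(multi)) {
    message(sum(multi), " site(s) flagged multi-allelic and excluded: ",
            paste(head(paste0(sites$chrom[multi], ":", sites$pos[multi]), 5),
                  collapse = ", "))
  }
  keep <- !multi
  sites$alt <- NUC[ai]
  ref_count <- vapply(seq_len(np), function(j)
    counts[cbind(seq_len(nrow(m)), j, ri)], integer(nrow(m)))
  alt_count <- vapply(seq_len(np), function(j)
    counts[cbind(seq_len(nrow(m)), j, ai)], integer(nrow(m)))
  allele_count_panel(sites[keep, , drop = FALSE], samples,
                     ref_count[keep, , drop = FALSE],
                     alt_count[keep, , drop = FALSE])
}

#' Write an allele-count panel as a long-format TSV
#'
#' @param panel an \code{allele_count_panel}
#' @param path output path
#' @export
write_counts_tsv <- function(panel, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(panel$samples)), function(j) {
    data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
               population = panel$samples$population[j],
               sex = panel$samples$sex[j],
               generation = panel$samples$generation[j],
               ref_count = panel$ref_count[, j],
               alt_count = panel$alt_count[, j])
  }))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' simulate -> minor-allele definition -> coverage filter -> CMH scan ->
#' control-overlap filter -> logistic filter -> drift thresholds ->
#' verdicts -> selection quantitative genetics, returning one
#' machine-readable report. Identical configs (and therefore seeds) give
#' identical reports.
#'
#' @param config an \code{experiment_config}
#' @param panel optional pre-built \code{founder_panel} (one is generated
#'   from the config seed when omitted)
#' @param alpha CMH threshold; default Bonferroni 0.05 / n_sites
#' @param drift_reps Wright-Fisher replicates per threshold bin
#' @param ne_diploids effective size used for the drift table
#' @param out_dir optional directory for TSV/JSON artifacts
#' @return list of class \code{pipeline_report}
#' @export
run_pipeline <- function(config, panel = NULL, alpha = NULL,
                         drift_reps = 2000, ne_diploids = 42,
                         out_dir = NULL) {
  if (is.null(panel))
    panel <- generate_founder_panel(seed = substream_seed(config$seed, "panel"))
  sim <- simulate_experiment(panel, config)
  acp <- coverage_filter(sim$panel)
  minor <- define_minor_allele(acp, 0)
  if (is.null(alpha)) alpha <- 0.05 / nrow(acp$sites)
  scan <- afc_scan(acp, alpha = alpha, minor = minor)
  sch <- function(s) {
    pops <- unique(acp$samples$population[acp$samples$scheme == s])
    scan$significant[pops]
  }
  cand <- overlap_filter(sch("long"), sch("short"), sch("control"))
  logi <- if (length(cand)) logistic_filter(acp, cand, minor) else NULL
  survivors <- if (!is.null(logi)) logi$site[logi$pass] else integer()

  # drift thresholds and verdicts for survivors
  verdicts <- NULL
  if (length(survivors)) {
    gmax <- max(config$sequenced_generations)
    tr <- sim$trajectory
    fold <- function(p, is_alt) ifelse(is_alt, p, 1 - p)
    obs <- do.call(rbind, lapply(survivors, function(s) {
      sub <- tr[tr$site == s & tr$generation %in% c(0, gmax), ]
      mf <- fold(sub$true_freq, minor$minor_is_alt[s])
      q0 <- mean(mf[sub$generation == 0])
      dv <- abs(mean(mf[sub$generation == gmax & sub$scheme == "short"]) -
                mean(mf[sub$generation == gmax & sub$scheme == "long"]))
      data.frame(site = s, q0 = q0, divergence = dv,
                 chrom_mode = ifelse(panel$sites$chrom[s] == "X",
                                     "X", "autosome"))
    }))
    tabs <- list(
      autosome = drift_threshold_table(ne_diploids, t = gmax,
        n_reps = drift_reps, chrom_mode = "autosome",
        seed = substream_seed(config$seed, "drift-auto")),
      X = drift_threshold_table(ne_diploids, t = gmax, n_reps = drift_reps,
        chrom_mode = "X", seed = substream_seed(config$seed, "drift-x")))
    verdicts <- cbind(obs, exceeds = drift_verdict(obs, tabs))
  }

  # selection quantitative genetics per population
  h2 <- lapply(split(sim$phenotypes, sim$phenotypes$population), function(ph) {
    dirn <- switch(ph$scheme[1L], long = "high", short = "low", "random")
    gs <- generation_summary(ph, config$selection_fraction, dirn,
                             seed = substream_seed(config$seed,
                                                   paste0("gs-", ph$population[1L])))
    est <- realized_heritability(cumulative_series(gs))
    list(scheme = ph$scheme[1L], h2 = est$h2, se = est$se, p = est$p)
  })

  report <- structure(list(
    seed = config$seed, alpha = alpha,
    n_sites = nrow(acp$sites),
    n_significant = lapply(scan$significant, length),
    n_candidates = length(cand), candidates = cand,
    logistic = logi, n_pass = length(survivors), survivors = survivors,
    verdicts = verdicts, heritability = h2,
    version = as.character(utils::packageVersion("sleepsweep"))),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sync(sim$panel, file.path(out_dir, "counts.sync"))
    if (!is.null(logi))
      write.table(logi, file.path(out_dir, "logistic_filter.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_json <- function(report) {
  list(version = report$version, seed = report$seed, alpha = report$alpha,
       n_sites = report$n_sites, n_significant = report$n_significant,
       n_candidates = report$n_candidates, n_pass = report$n_pass,
       survivors = report$survivors,
       n_exceed_drift = if (is.null(report$verdicts)) 0
                        else sum(report$verdicts$exceeds, na.rm = TRUE),
       heritability = report$heritability)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("sleepsweep pipeline report (seed", x$seed, ")\n")
  cat("  sites:", x$n_sites, " candidates:", x$n_candidates,
      " logistic pass:", x$n_pass, "\n")
  if (!is.null(x$verdicts))
    cat("  exceed drift bound:", sum(x$verdicts$exceeds, na.rm = TRUE), "\n")
  invisible(x)
}
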
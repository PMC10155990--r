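#' Analyze one imaging session end to end
#'
#' Runs spike inference, reverse correlation, the three-criterion
#' responsiveness classification, tuning metrics, and per-neuron ocular
#' dominance for every neuron of a session, independently per eye.
#'
#' @param session A `synthetic_session` (dF/F matrices per eye plus
#'   schedules), or any list with the same fields.
#' @param smoothing,threshold Spike-inference parameters, see
#'   [infer_spike_rate()].
#' @param sf_sig Also run the per-SF significance tests (slower)?
#' @return List with `stats` (per neuron x eye: optimal delay, SNR, SR,
#'   thresholds, responsive flag), `tuning` (per responsive neuron x eye:
#'   preferred orientation/SF, widths, dF/F at preferred, per-SF
#'   significance), and `od` (per neuron: ODI, category, delta_ori,
#'   per-eye dF/F).
#' @export
analyze_session <- function(session, smoothing = 3, threshold = 2,
                            sf_sig = FALSE) {
  isr <- session_isr(session, smoothing, threshold)
  n <- ncol(session$dff$contra)
  ids <- session$pop$id
  stats_rows <- list()
  tensors <- list(contra = vector("list", n), ipsi = vector("list", n))
  for (eye in c("contra", "ipsi")) {
    sch <- session$schedules[[eye]]
    for (j in seq_len(n)) {
      tens <- reverse_correlate(isr[[eye]][, j], sch)
      tensors[[eye]][[j]] <- tens
      od <- optimal_delay(tens)
      snr <- suppressWarnings(compute_snr(tens))
      sr <- 0
      pref <- NULL
      if (!is.na(od$delay)) {
        pref <- suppressWarnings(preferred_stimulus(tens, od$delay))
        if (!is.null(pref))
          sr <- compute_spike_ratio(isr[[eye]][, j], sch, pref$ori,
                                    pref$sf, od$delay)
      }
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        id = ids[j], eye = eye,
        optimal_delay = if (is.na(od$delay)) NA_integer_ else od$delay,
        time_locked = od$time_locked, snr = snr, sr = sr,
        pref_ori_cell = if (is.null(pref)) NA_real_ else pref$ori,
        pref_sf_cell = if (is.null(pref)) NA_real_ else pref$sf)
    }
  }
  stats_df <- do.call(rbind, stats_rows)
  stats_df <- classify_population(stats_df)
  tuning_rows <- list()
  for (k in which(stats_df$responsive)) {
    eye <- stats_df$eye[k]
    j <- match(stats_df$id[k], ids)
    tens <- tensors[[eye]][[j]]
    delay <- stats_df$optimal_delay[k]
    di <- match(delay, tens$delays)
    pref <- preferred_stimulus(tens, delay)
    if (is.null(pref)) next
    O_n <- tens$z[di, , pref$sf_idx]
    Sf_k <- tens$z[di, pref$ori_idx, seq_along(tens$sf_grid)]
    O_n[!is.finite(O_n)] <- 0
    Sf_k[!is.finite(Sf_k)] <- 0
    po <- preferred_orientation(O_n, tens$ori_grid)
    psf <- preferred_sf(Sf_k, tens$sf_grid)
    ofw <- orientation_fwhm(O_n, tens$ori_grid)
    sfw <- sf_fwhm(Sf_k, tens$sf_grid)
    sch <- session$schedules[[eye]]
    dffp <- dff_at_preferred(session$dff[[eye]][, j], sch, pref$ori,
                             pref$sf, delay)
    sig <- rep(NA, length(tens$sf_grid))
    if (sf_sig) {
      sm <- isr_samples_by_sf(isr[[eye]][, j], sch, delay)
      sig <- as.logical(sf_significance(sm$sf_samples, sm$blank_samples))
    }
    tuning_rows[[length(tuning_rows) + 1]] <- cbind(
      data.frame(id = stats_df$id[k], eye = eye, pref_ori = po,
                 ori_fwhm = ofw$fwhm, pref_sf = psf, sf_fwhm = sfw$fwhm,
                 dff_pref = dffp),
      stats::setNames(as.data.frame(as.list(sig)),
                      paste0("sf_sig_", seq_along(sig))))
  }
  tuning_df <- if (length(tuning_rows)) do.call(rbind, tuning_rows) else
    NULL
  od_rows <- lapply(ids, function(id) {
    rc <- stats_df$responsive[stats_df$id == id & stats_df$eye == "contra"]
    ri <- stats_df$responsive[stats_df$id == id & stats_df$eye == "ipsi"]
    gdff <- function(eye) {
      if (is.null(tuning_df)) return(0)
      v <- tuning_df$dff_pref[tuning_df$id == id & tuning_df$eye == eye]
      if (length(v)) v[1] else 0
    }
    gori <- function(eye) {
      if (is.null(tuning_df)) return(NA_real_)
      v <- tuning_df$pref_ori[tuning_df$id == id & tuning_df$eye == eye]
      if (length(v)) v[1] else NA_real_
    }
    cd <- gdff("contra"); idf <- gdff("ipsi")
    res <- suppressWarnings(neuron_odi(cd, idf, isTRUE(rc), isTRUE(ri)))
    dori <- if (res$category == "B")
      delta_ori(wrap180(gori("contra")), wrap180(gori("ipsi"))) else
        NA_real_
    data.frame(id = id, odi = res$odi, category = res$category,
               delta_ori = dori, C_dff = cd, I_dff = idf)
  })
  list(stats = stats_df, tuning = tuning_df, od = do.call(rbind, od_rows))
}

#' Percent of responsive neurons with significant responses per SF
#'
#' Per mouse and eye: 100 x (responsive neurons significant at SF k) /
#' (responsive neurons). When two or more groups are supplied, a two-factor
#' analysis of variance (group x SF, mouse as replicate) is run per eye,
#' with per-SF group contrasts (Welch t) corrected by Sidak's method for 8
#' comparisons.
#'
#' @param tuning_df Tuning tables with columns `mouse`, `group`, `eye`,
#'   and `sf_sig_1..8` (one row per responsive neuron x eye).
#' @return List with `percent` (mouse x SF long data.frame) and `tests`
#'   (per-eye list with the ANOVA table and Sidak-adjusted contrasts), or
#'   `tests = NULL` with fewer than 2 groups.
#' @export
percent_responsive_per_sf <- function(tuning_df) {
  sig_cols <- grep("^sf_sig_", names(tuning_df), value = TRUE)
  rows <- list()
  for (m in unique(tuning_df$mouse)) for (eye in unique(tuning_df$eye)) {
    sel <- tuning_df$mouse == m & tuning_df$eye == eye
    if (!any(sel)) {
      warning("mouse ", m, " has zero responsive neurons for eye ", eye)
      next
    }
    for (k in seq_along(sig_cols)) {
      rows[[length(rows) + 1]] <- data.frame(
        mouse = m, group = tuning_df$group[sel][1], eye = eye, sf = k,
        percent = 100 * mean(tuning_df[[sig_cols[k]]][sel], na.rm = TRUE))
    }
  }
  pct <- do.call(rbind, rows)
  tests <- NULL
  if (length(unique(pct$group)) >= 2) {
    tests <- lapply(split(pct, pct$eye), function(d) {
      d$sf <- factor(d$sf)
      d$group <- factor(d$group)
      fit <- stats::aov(percent ~ group * sf, data = d)
      contrasts <- do.call(rbind, lapply(levels(d$sf), function(k) {
        dk <- d[d$sf == k, ]
        if (length(unique(dk$group)) < 2 ||
            min(table(dk$group)) < 2)
          return(data.frame(sf = k, p_raw = NA, p_sidak = NA))
        p <- stats::t.test(percent ~ group, data = dk)$p.value
        data.frame(sf = k, p_raw = p, p_sidak = 1 - (1 - p)^8)
      }))
      list(anova = stats::anova(fit), contrasts = contrasts)
    })
  }
  list(percent = pct, tests = tests)
}

#' Compare two samples with a named classical test
#'
#' @param a,b Numeric samples (equal length for paired tests).
#' @param test One of `"ks"`, `"mw"`, `"welch_t"`, `"paired_t"`,
#'   `"kw_dunn"`.
#' @return List with `test`, `statistic`, `p_value`, and the two empirical
#'   CDFs (`cdf_a`, `cdf_b`).
#' @export
compare_distributions <- function(a, b,
                                  test = c("ks", "mw", "welch_t",
                                           "paired_t", "kw_dunn")) {
  test <- match.arg(test)
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  res <- switch(test,
    ks = {
      h <- suppressWarnings(stats::ks.test(a, b))
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    mw = {
      h <- stats::wilcox.test(a, b)
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    welch_t = {
      h <- stats::t.test(a, b)
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    paired_t = {
      if (length(a) != length(b)) stop("paired test needs equal lengths")
      h <- stats::t.test(a, b, paired = TRUE)
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    kw_dunn = {
      h <- stats::kruskal.test(list(a, b))
      list(statistic = unname(h$statistic), p_value = h$p.value)
    })
  ecdf_of <- function(x) list(value = sort(x),
                              cum_fraction = seq_along(x) / length(x))
  c(list(test = test), res,
    list(cdf_a = ecdf_of(a), cdf_b = ecdf_of(b)))
}

#' Simulate and analyze one synthetic mouse
#'
#' Builds a ground-truth population, simulates the pre-deprivation session
#' and (optionally) the post-MD session from the MD-perturbed population,
#' and analyzes each with [analyze_session()].
#'
#' @param n_neurons Population size.
#' @param duration Session length, seconds.
#' @param md Apply the MD perturbation and simulate the second timepoint?
#' @param md_model MD model, see [default_md_model()].
#' @param priors Tuning priors.
#' @param seed Integer RNG seed (sub-seeds are derived from it).
#' @param sf_sig Run per-SF significance tests?
#' @return List with `pop`, `analysis_t1` and, when `md`, `pop_md` and
#'   `analysis_t2`.
#' @export
simulate_mouse <- function(n_neurons = 120, duration = 600, md = FALSE,
                           md_model = default_md_model(),
                           priors = default_tuning_priors(), seed,
                           sf_sig = FALSE) {
  if (missing(seed)) stop("seed is required")
  pop <- sample_population(n_neurons, priors = priors, seed = seed)
  sch <- list(
    contra = make_stimulus_schedule(duration, eye = "contra",
                                    seed = seed + 1000L),
    ipsi = make_stimulus_schedule(duration, eye = "ipsi",
                                  seed = seed + 2000L))
  s1 <- simulate_session(pop, sch, seed = seed + 3000L)
  out <- list(pop = pop,
              analysis_t1 = analyze_session(s1, sf_sig = sf_sig),
              session_t1 = s1)
  if (md) {
    pop2 <- apply_md_transition(pop, md_model, priors, seed = seed + 4000L)
    sch2 <- list(
      contra = make_stimulus_schedule(duration, eye = "contra",
                                      seed = seed + 5000L),
      ipsi = make_stimulus_schedule(duration, eye = "ipsi",
                                    seed = seed + 6000L))
    s2 <- simulate_session(pop2, sch2, seed = seed + 7000L)
    out$pop_md <- pop2
    out$analysis_t2 <- analyze_session(s2, sf_sig = sf_sig)
    out$session_t2 <- s2
  }
  out
}

#' Run the full simulation-analysis pipeline for several mice
#'
#' Simulates `n_mice` mice per group (`P28` nondeprived; `P32MD` after the
#' monocular-deprivation perturbation), analyzes every session, and writes
#' per-mouse summary and per-neuron tables plus a provenance JSON under
#' `outdir`.
#'
#' @param config List with `n_mice` (named, per group), `n_neurons`,
#'   `duration`, `seed`, optional `md_model`, `priors`, `sf_sig`.
#' @param outdir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return List with `mouse_summary` (data.frame) and `neuron_od`
#'   (data.frame), invisibly also written as TSVs.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(is.list(config), !is.null(config$seed))
  n_mice <- config$n_mice %||% c(P28 = 3, P32MD = 3)
  n_neurons <- config$n_neurons %||% 120
  duration <- config$duration %||% 600
  mdm <- config$md_model %||% default_md_model()
  priors <- config$priors %||% default_tuning_priors()
  sf_sig <- isTRUE(config$sf_sig)
  summaries <- list()
  neuron_rows <- list()
  midx <- 0
  for (grp in names(n_mice)) {
    for (i in seq_len(n_mice[[grp]])) {
      midx <- midx + 1
      seed_i <- config$seed + midx * 10000L
      sim <- simulate_mouse(n_neurons, duration, md = grp == "P32MD",
                            md_model = mdm, priors = priors,
                            seed = seed_i, sf_sig = sf_sig)
      ana <- if (grp == "P32MD") sim$analysis_t2 else sim$analysis_t1
      ms <- mouse_odi_summaries(ana$od)
      mouse_id <- sprintf("%s_m%02d", grp, i)
      summaries[[midx]] <- data.frame(
        mouse = mouse_id, group = grp, mean_odi = ms$mean_odi,
        summed_odi = ms$summed_odi, n_responsive = ms$n_responsive,
        mean_C_dff = mean(ana$od$C_dff[ana$od$category %in% c("C", "B")]),
        mean_I_dff = mean(ana$od$I_dff[ana$od$category %in% c("I", "B")]))
      nod <- ana$od
      nod$mouse <- mouse_id
      nod$group <- grp
      neuron_rows[[midx]] <- nod
    }
  }
  mouse_summary <- do.call(rbind, summaries)
  neuron_od <- do.call(rbind, neuron_rows)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(mouse_summary, file.path(outdir, "mouse_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(neuron_od, file.path(outdir, "neuron_od.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    prov <- list(config = config[setdiff(names(config),
                                         c("md_model", "priors"))],
                 version = as.character(utils::packageVersion("odplast")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(mouse_summary = mouse_summary, neuron_od = neuron_od)
}

#' Ingest a deposited-style per-neuron tuning table
#'
#' Reads a tabular file with one row per neuron (columns: neuron id, mouse
#' id, group, per-eye preferred orientation/SF and dF/F, ODI, OD category)
#' and computes the group-level summaries (per-mouse mean and summed ODI,
#' binocular-matching distributions) without any simulation.
#'
#' @param path TSV/CSV file path.
#' @return List with `neurons` (the table), `mouse_summary`, and
#'   `matching` (per-group binocular delta-ori samples).
#' @export
ingest_tuning_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("neuron", "mouse", "group", "odi", "category", "C_dff",
            "I_dff")
  if (!all(need %in% names(tab)))
    stop("tuning table must contain columns: ",
         paste(need, collapse = ", "))
  ms <- do.call(rbind, lapply(split(tab, tab$mouse), function(d) {
    s <- mouse_odi_summaries(d)
    data.frame(mouse = d$mouse[1], group = d$group[1],
               mean_odi = s$mean_odi, summed_odi = s$summed_odi,
               n_responsive = s$n_responsive)
  }))
  rownames(ms) <- NULL
  matching <- NULL
  if (all(c("pref_ori_C", "pref_ori_I") %in% names(tab))) {
    b <- tab[tab$category == "B", ]
    matching <- data.frame(
      group = b$group,
      delta_ori = delta_ori(wrap180(b$pref_ori_C), wrap180(b$pref_ori_I)))
  }
  list(neurons = tab, mouse_summary = ms, matching = matching)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
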
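#' Configure a full pipeline run
#'
#' Bundles every stage's parameters plus the single global seed from
#' which all per-stage random substreams are derived. Defaults mirror the
#' reference design: 10 subjects x 800 word-pairs, both conditions,
#' 512 Hz raw simulation resampled to 256 Hz, Woody estimation on Pz with
#' 4 iterations, and the documented matching cutoffs.
#'
#' @param n_subjects,n_pairs Design size.
#' @param conditions Conditions to simulate (speeded is required when
#'   delayed is present, for template re-use).
#' @param seed Global integer seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @param montage_size 32 (full) or 9 (reduced, faster) channels.
#' @param sfreq_raw,target_hz Simulation and analysis rates.
#' @param woody A [woody_config()].
#' @param n_per_subject Fixed-latency group size per subject (default 75).
#' @param as_low_max,as_high_min,p3_short_max,p3_long_min Matching cutoffs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 10, n_pairs = 800,
                            conditions = c("speeded", "delayed"),
                            seed = 1, out_dir = tempfile("erprun"),
                            montage_size = 32, sfreq_raw = 512,
                            target_hz = 256, woody = woody_config(),
                            n_per_subject = 75,
                            as_low_max = 1, as_high_min = 18,
                            p3_short_max = 0.5, p3_long_min = 0.6) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if ("delayed" %in% conditions && !"speeded" %in% conditions)
    stopf("pipeline_config: the delayed condition needs the speeded condition's template")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full simulate-preprocess-estimate-match-test pipeline
#'
#' For each subject and condition: simulate behaviour and continuous EEG,
#' run the standard preprocessing chain, estimate single-trial P3
#' latencies (iterative Woody in the speeded condition; the subject's
#' final speeded template re-used for the delayed condition), bin trials
#' 8 ways by AS and RT, build competition and fixed-latency matched
#' groups, and contrast them at Pz over 400-500 ms. All randomness flows
#' from the global seed through named substreams. Outputs (behaviour,
#' latencies, bin summaries, group tables, contrasts, manifest) are
#' written as TSV/JSON under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`behavior`,
#'   `latencies`, `bins`, `groups`, `contrasts`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  save_tsv <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    art[[name]] <<- p
    p
  }

  pairs <- generate_stimulus_list(n_total = config$n_pairs,
                                  n_zero = max(1, round(config$n_pairs / 8)),
                                  n_top = max(1, round(config$n_pairs / 8)),
                                  seed = substream_seed(config$seed, "stimuli"))
  save_tsv(pairs, "stimulus_list")

  behavior <- list(); latencies <- list(); bins <- list()
  epochs_all <- list(); ground_truth <- list()
  # speeded runs first: its final template seeds the delayed condition
  config$conditions <- intersect(c("speeded", "delayed"), config$conditions)
  for (cond in config$conditions) {
    profiles <- subject_profiles(config$n_subjects, cond,
                                 seed = substream_seed(config$seed,
                                                       paste0("profiles_", cond)))
    behavior[[cond]] <- simulate_behavior(
      pairs, profiles, cond,
      seed = substream_seed(config$seed, paste0("behavior_", cond)))
  }

  for (cond in config$conditions) {
    simcfg <- simulation_config(cond, sfreq_raw = config$sfreq_raw,
                                channel_names = default_montage(config$montage_size))
    per_subj <- list()
    lat_rows <- list()
    gt_rows <- list()
    for (s in unique(behavior[[cond]]$subject_id)) {
      tr <- behavior[[cond]][behavior[[cond]]$subject_id == s, ]
      sim <- simulate_eeg(tr, simcfg,
                          seed = substream_seed(config$seed,
                                                paste0("eeg_", cond, "_", s)))
      gt_rows[[s]] <- sim$ground_truth
      rec <- bandpass_iir(sim$recording, 0.1, 50)
      rec <- resample_recording(rec, config$target_hz)
      rec <- regress_eog(rec)
      rec15 <- bandpass_iir(rec, 0.5, 15)
      ep <- epoch_recording(rec15, "target", metadata = tr)
      ep <- baseline_correct(ep)
      ep <- reject_no_response(ep)
      per_subj[[s]] <- ep
      # matching band: filter the continuous signal, then cut
      wep <- woody_epochs(rec, tr, config$woody)
      if (cond == "speeded") {
        lt <- estimate_latencies(wep, wep$trials$rt_s, config$woody,
                                 prefilter = FALSE)
        attr(lt, "subject") <- s
      } else {
        tpl <- attr(latencies$speeded[[s]], "template")
        lt <- reuse_template(tpl, wep, config$woody, prefilter = FALSE)
      }
      lat_rows[[s]] <- lt
    }
    latencies[[cond]] <- lat_rows
    epochs_all[[cond]] <- per_subj
    ground_truth[[cond]] <- do.call(rbind, gt_rows)
    lat_df <- do.call(rbind, lapply(lat_rows, as.data.frame))
    save_tsv(lat_df, paste0("latencies_", cond))
    save_tsv(behavior[[cond]], paste0("behavior_", cond))
    kept <- behavior[[cond]][!behavior[[cond]]$missed, ]
    bins[[cond]] <- bin_trials(kept, key = "as", n_bins = 8)
    save_tsv(bins[[cond]]$summary, paste0("bins_as_", cond))
    if (cond == "speeded")
      save_tsv(bin_trials(kept, key = "rt", n_bins = 8)$summary,
               "bins_rt_speeded")
  }

  groups <- list(); contrasts <- list()
  if ("speeded" %in% config$conditions) {
    sp <- behavior$speeded[!behavior$speeded$missed, ]
    lat_df <- do.call(rbind, lapply(latencies$speeded, as.data.frame))
    sp$latency_s <- lat_df$latency_s[match(sp$trial_id, lat_df$trial_id)]
    groups$fixed <- build_fixed_latency_groups(
      sp, as_low_max = config$as_low_max, as_high_min = config$as_high_min,
      n_per_subject = config$n_per_subject)
    save_tsv(groups$fixed, "groups_fixed_latency")
    sp_epochs <- pool_epochs(epochs_all$speeded)
    contrasts$fixed <- contrast_groups(sp_epochs, groups$fixed,
                                       groups = c("lowAS", "highAS"))
    if ("delayed" %in% config$conditions) {
      del <- behavior$delayed[!behavior$delayed$missed, ]
      groups$competition <- build_competition_groups(
        sp, del, as_low_max = config$as_low_max,
        as_high_min = config$as_high_min,
        p3_short_max = config$p3_short_max,
        p3_long_min = config$p3_long_min,
        seed = substream_seed(config$seed, "competition"))
      save_tsv(groups$competition, "groups_competition")
      contrasts$competition_speeded <-
        contrast_groups(sp_epochs, groups$competition, groups = c(1, 2))
      contrasts$competition_delayed <-
        contrast_groups(pool_epochs(epochs_all$delayed), groups$competition,
                        groups = c(3, 4))
    }
    con_df <- do.call(rbind, lapply(names(contrasts), function(nm) {
      k <- contrasts[[nm]]
      data.frame(contrast = nm, mean_1 = k$group_means[1],
                 mean_2 = k$group_means[2], difference = k$difference,
                 w = k$lme$w, t = k$lme$t, p = k$lme$p)
    }))
    save_tsv(con_df, "contrasts")
  }

  manifest <- data.frame(artifact = names(art),
                         path = unlist(art, use.names = FALSE),
                         md5 = unname(tools::md5sum(unlist(art, use.names = FALSE))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_echo <- config
  cfg_echo$woody <- unclass(cfg_echo$woody)
  jsonlite::write_json(lapply(unclass(cfg_echo), function(x)
    if (is.function(x)) NULL else x),
    file.path(config$out_dir, "run_config.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(behavior = behavior, latencies = latencies, bins = bins,
                 groups = groups, contrasts = contrasts,
                 ground_truth = ground_truth, epochs = epochs_all,
                 out_dir = config$out_dir))
}

#' Concatenate per-subject epoch sets
#' @param epoch_list Named list of `epoch_set`s with identical shape.
#' @return One pooled `epoch_set`.
#' @export
pool_epochs <- function(epoch_list) {
  stopifnot(length(epoch_list) >= 1)
  d <- dim(epoch_list[[1]]$data)
  n <- sum(vapply(epoch_list, function(e) dim(e$data)[1], 1L))
  dat <- array(0, c(n, d[2], d[3]))
  trials <- list(); k <- 0
  for (e in epoch_list) {
    m <- dim(e$data)[1]
    if (m > 0) dat[(k + 1):(k + m), , ] <- e$data
    k <- k + m
    trials[[length(trials) + 1L]] <- e$trials
  }
  first <- epoch_list[[1]]
  epoch_set(dat, first$t0, first$sfreq, first$channel_names, first$lock,
            do.call(rbind, trials), log = first$log)
}

#' Summarize a pipeline run directory
#'
#' Regenerates the run's summary tables from the TSV artifacts: the
#' 8-row bin descriptives per condition (mean/sd AS, mean/sd RT, response
#' ratio), and the group contrasts with sign and monotonicity flags.
#' Missing artifacts are listed and a partial report is produced.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List: `bins` (named list of `data.frame`s), `contrasts`
#'   (`data.frame` with `sign` column), `missing` (character).
#' @export
pipeline_report <- function(run_dir) {
  rd <- function(name) {
    p <- file.path(run_dir, paste0(name, ".tsv"))
    if (!file.exists(p)) return(NULL)
    utils::read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  }
  wanted <- c("bins_as_speeded", "bins_rt_speeded", "bins_as_delayed",
              "contrasts")
  found <- lapply(wanted, rd)
  names(found) <- wanted
  missing <- wanted[vapply(found, is.null, TRUE)]
  bins <- found[grepl("^bins", names(found))]
  bins <- bins[!vapply(bins, is.null, TRUE)]
  for (nm in names(bins)) {
    b <- bins[[nm]]
    b$rt_monotone_up <- !is.unsorted(b$mean_rt)
    b$ratio_monotone_down <- !is.unsorted(rev(b$response_ratio))
    bins[[nm]] <- b
  }
  contrasts <- found$contrasts
  if (!is.null(contrasts))
    contrasts$sign <- ifelse(contrasts$difference > 0, "positive", "negative")
  list(bins = bins, contrasts = contrasts, missing = missing)
}
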
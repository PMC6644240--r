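#' @name behavior
#' @title Trial-level Stroop session handling
#' @description Loading, sequence annotation, exclusion rules, and
#'   congruency / congruency-sequence effect tables for two-choice Stroop
#'   sessions.
NULL

session_columns <- function() {
  c("participant", "condition", "trial_idx", "phase", "word", "font_color",
    "congruency", "prev_congruency", "response", "correct", "rt_ms", "isi_s")
}

#' Load trial-level sessions from CSV
#'
#' Reads a session table in the package schema, types the columns, and
#' validates internal consistency: congruency is recomputed from
#' word/font_color and cross-checked against the stored column, and RTs
#' must lie in (0, 1500] ms (the task's trial length).
#'
#' @param path CSV file with columns `participant, condition, trial_idx,
#'   phase, word, font_color, congruency, prev_congruency, response,
#'   correct, rt_ms, isi_s` (`prev_congruency` and `isi_s` may be empty).
#' @return data.frame of trial records.
#' @export
load_sessions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(session_columns(), c("prev_congruency", "isi_s")),
                     names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(df$prev_congruency)) df$prev_congruency <- NA_character_
  if (is.null(df$isi_s)) df$isi_s <- NA_real_
  df$correct <- as.logical(df$correct)
  recomputed <- ifelse(df$word == df$font_color, "congruent", "incongruent")
  bad <- which(df$congruency != recomputed)
  if (length(bad))
    stop("congruency inconsistent with word/font_color in rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad_rt <- which(!is.finite(df$rt_ms) | df$rt_ms <= 0 | df$rt_ms > 1500)
  if (length(bad_rt))
    stop("rt_ms outside (0, 1500] in rows: ",
         paste(utils::head(bad_rt, 10), collapse = ", "), call. = FALSE)
  df[session_columns()]
}

#' Write sessions to CSV
#' @param trials data.frame of trial records.
#' @param path output CSV path.
#' @export
write_sessions <- function(trials, path) {
  write.csv(trials[intersect(session_columns(), names(trials))], path,
            row.names = FALSE)
  invisible(path)
}

#' Annotate previous-trial congruency (CPT)
#'
#' Fills `prev_congruency`: for main-phase trial k it is the congruency of
#' main-phase trial k-1 within the same (participant, condition) session;
#' the first main trial of a session gets `"none"`. Practice trials never
#' feed the sequence and are themselves tagged `"none"`.
#'
#' @param trials data.frame of trial records, ordered by `trial_idx`
#'   within session.
#' @return the trials with `prev_congruency` filled.
#' @export
annotate_sequence <- function(trials) {
  key <- interaction(trials$participant, trials$condition, drop = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  prev <- rep("none", nrow(trials))
  for (i in idx) {
    if (is.unsorted(trials$trial_idx[i]))
      stop("trials not ordered by trial_idx within session", call. = FALSE)
    main <- i[trials$phase[i] == "main"]
    if (length(main) > 1)
      prev[main[-1]] <- trials$congruency[main[-length(main)]]
  }
  trials$prev_congruency <- prev
  trials
}

#' Apply trial exclusions
#'
#' Practice trials are always dropped. For RT analyses (`for_rt = TRUE`),
#' error trials and the single trial immediately following an error
#' (posterror) are dropped as well; for accuracy analyses all main trials
#' are retained. Idempotent.
#'
#' @param trials annotated trial records (see [annotate_sequence()]).
#' @param for_rt logical; apply the error/posterror exclusion.
#' @return filtered data.frame.
#' @export
apply_exclusions <- function(trials, for_rt = TRUE) {
  trials <- trials[trials$phase == "main", , drop = FALSE]
  if (!for_rt) return(trials)
  key <- interaction(trials$participant, trials$condition, drop = TRUE)
  keep <- rep(TRUE, nrow(trials))
  for (i in split(seq_len(nrow(trials)), key)) {
    err <- !trials$correct[i]
    posterr <- c(FALSE, err[-length(err)])
    keep[i] <- !err & !posterr
  }
  trials[keep, , drop = FALSE]
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

condition_effects <- function(tr) {
  cct <- c(congruent = mean_or_na(tr$rt_ms[tr$congruency == "congruent"]),
           incongruent = mean_or_na(tr$rt_ms[tr$congruency == "incongruent"]))
  cells <- matrix(NA_real_, 2, 2,
                  dimnames = list(cct = c("congruent", "incongruent"),
                                  cpt = c("congruent", "incongruent")))
  for (cc in rownames(cells)) for (cp in colnames(cells))
    cells[cc, cp] <- mean_or_na(
      tr$rt_ms[tr$congruency == cc & tr$prev_congruency == cp])
  stroop_by_cpt <- cells["incongruent", ] - cells["congruent", ]
  list(cells_cct = cct,
       cells_cct_cpt = cells,
       stroop_effect = unname(cct["incongruent"] - cct["congruent"]),
       stroop_by_cpt = stroop_by_cpt,
       gratton = unname(stroop_by_cpt["congruent"] -
                          stroop_by_cpt["incongruent"]),
       n_trials = nrow(tr))
}

#' Congruency and congruency-sequence effect table
#'
#' Per stimulation condition: mean RT per current-trial congruency (CCT)
#' cell and per CCT x previous-trial congruency (CPT) cell, the Stroop
#' effect (mean incongruent minus mean congruent RT), the Stroop effect
#' within each CPT stratum, and the Gratton contrast
#' (Stroop given CPT congruent minus Stroop given CPT incongruent).
#' Trials with `prev_congruency == "none"` enter the overall Stroop effect
#' but not the CPT-stratified cells. Empty cells are reported as `NA`.
#'
#' @param trials exclusion-applied RT trials (see [apply_exclusions()]).
#' @param acc_trials optional all-trials set for accuracy cell means.
#' @return `dmc_effect_table`: a named list (one element per condition).
#' @export
effect_table <- function(trials, acc_trials = NULL) {
  out <- lapply(split(trials, trials$condition), condition_effects)
  if (!is.null(acc_trials)) {
    acc <- split(acc_trials, acc_trials$condition)
    for (cond in names(out)) {
      tr <- acc[[cond]]
      out[[cond]]$accuracy_cct <- c(
        congruent = mean_or_na(tr$correct[tr$congruency == "congruent"]),
        incongruent = mean_or_na(tr$correct[tr$congruency == "incongruent"]))
    }
  }
  structure(out, class = "dmc_effect_table")
}

#' Build an effect table from reported summary effects
#'
#' Constructs a `dmc_effect_table` directly from per-condition effect
#' estimates (e.g. published model estimates of the Stroop effect and its
#' CPT strata), so [delta_vs_sham()] can be applied to printed values as
#' well as to computed tables. The Gratton contrast is derived from the
#' strata when both are given.
#'
#' @param summary data.frame with columns `condition`, `stroop`, and
#'   optionally `stroop_cpt_congruent`, `stroop_cpt_incongruent`.
#' @return `dmc_effect_table`.
#' @examples
#' tab <- effect_table_from_summary(data.frame(
#'   condition = c("sham", "6hz"), stroop = c(46.2, 33.8)))
#' delta_vs_sham(tab)  # 12.4 ms
#' @export
effect_table_from_summary <- function(summary) {
  stopifnot(all(c("condition", "stroop") %in% names(summary)))
  get_col <- function(nm) if (nm %in% names(summary)) summary[[nm]] else
    rep(NA_real_, nrow(summary))
  sc <- get_col("stroop_cpt_congruent")
  si <- get_col("stroop_cpt_incongruent")
  out <- lapply(seq_len(nrow(summary)), function(i) {
    sb <- c(congruent = sc[i], incongruent = si[i])
    list(cells_cct = NULL, cells_cct_cpt = NULL,
         stroop_effect = summary$stroop[i],
         stroop_by_cpt = sb,
         gratton = unname(sb["congruent"] - sb["incongruent"]),
         n_trials = NA_integer_)
  })
  names(out) <- as.character(summary$condition)
  structure(out, class = "dmc_effect_table")
}

#' @export
print.dmc_effect_table <- function(x, ...) {
  for (cond in names(x)) {
    e <- x[[cond]]
    cat(sprintf("%s: Stroop = %.1f ms", cond, e$stroop_effect))
    if (!is.na(e$gratton))
      cat(sprintf(", Stroop|cpt=c = %.1f, Stroop|cpt=i = %.1f, Gratton = %.1f ms",
                  e$stroop_by_cpt["congruent"], e$stroop_by_cpt["incongruent"],
                  e$gratton))
    cat("\n")
  }
  invisible(x)
}

#' Tidy export of an effect table
#' @param x a `dmc_effect_table`.
#' @param ... unused.
#' @return data.frame with one row per condition x effect.
#' @export
as.data.frame.dmc_effect_table <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(cond) {
    e <- x[[cond]]
    data.frame(condition = cond,
               effect = c("stroop", "stroop_cpt_congruent",
                          "stroop_cpt_incongruent", "gratton"),
               value = c(e$stroop_effect, e$stroop_by_cpt["congruent"],
                         e$stroop_by_cpt["incongruent"], e$gratton),
               row.names = NULL)
  }))
}

#' Sham minus active effect differences
#'
#' Arithmetic differences (sham minus each active condition) of the Stroop
#' effect, the CPT-stratified Stroop effects, and the Gratton contrast.
#'
#' @param effects a `dmc_effect_table` containing a `"sham"` condition and
#'   at least one other condition.
#' @param sham name of the reference condition.
#' @return data.frame with columns `condition`, `effect`, `sham`, `active`,
#'   `delta` (sham - active).
#' @export
delta_vs_sham <- function(effects, sham = "sham") {
  stopifnot(inherits(effects, "dmc_effect_table"))
  if (!sham %in% names(effects))
    stop("no '", sham, "' condition in the effect table", call. = FALSE)
  actives <- setdiff(names(effects), sham)
  if (!length(actives))
    stop("no active condition to compare against sham", call. = FALSE)
  s <- effects[[sham]]
  pull <- function(e) c(stroop = e$stroop_effect,
                        stroop_cpt_congruent = unname(e$stroop_by_cpt["congruent"]),
                        stroop_cpt_incongruent = unname(e$stroop_by_cpt["incongruent"]),
                        gratton = e$gratton)
  do.call(rbind, lapply(actives, function(cond) {
    a <- pull(effects[[cond]])
    b <- pull(s)
    data.frame(condition = cond, effect = names(b),
               sham = unname(b), active = unname(a),
               delta = unname(b - a), row.names = NULL)
  }))
}
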
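#' Build a delayed-match-to-sample task schedule
#'
#' Two blocks of eight trials. Each trial presents two target images for
#' 3 s (encoding, followed by a 2-s consolidation gap), then a sequence of
#' 12 test images - 6 target presentations and 6 distinct distractors,
#' shuffled - each shown for 1 s with a jittered inter-stimulus gap drawn
#' uniformly from \[1.6, 1.8\] s. The match response hand is the dominant
#' hand in block 1 and the non-dominant hand in block 2. A trial lasts
#' about 40 s; trial duration is emergent, not enforced.
#'
#' @param seed integer seed; schedules are deterministic given the seed.
#' @param n_blocks,trials_per_block,items_per_trial structural counts
#'   (defaults 2, 8, 12).
#' @param n_targets number of target images per trial (default 2).
#' @param encoding_s target presentation duration in seconds.
#' @param gap_s post-encoding consolidation gap in seconds.
#' @param jitter_range inter-stimulus jitter bounds in seconds.
#' @param image_pool number of distinct image identifiers available.
#' @return An object of class `task_schedule`: list with `trials` (one row
#'   per trial: trial, block, response_hand, target image ids) and `items`
#'   (one row per test item: trial, block, item, image, is_target,
#'   onset_s).
#' @export
build_task_schedule <- function(seed = 1, n_blocks = 2,
                                trials_per_block = 8, items_per_trial = 12,
                                n_targets = 2, encoding_s = 3, gap_s = 2,
                                jitter_range = c(1.6, 1.8),
                                image_pool = 260) {
  set.seed(seed)
  n_trials <- n_blocks * trials_per_block
  n_distract <- items_per_trial %/% 2
  if (image_pool < n_targets + n_distract)
    stop("image pool too small for one trial")
  trials <- data.frame(trial = seq_len(n_trials),
                       block = rep(seq_len(n_blocks),
                                   each = trials_per_block),
                       response_hand = rep(c("dominant", "non_dominant"),
                                           each = trials_per_block,
                                           length.out = n_trials),
                       stringsAsFactors = FALSE)
  items <- vector("list", n_trials)
  targets <- matrix(NA_integer_, n_trials, n_targets)
  for (tr in seq_len(n_trials)) {
    imgs <- sample.int(image_pool, n_targets + n_distract)
    tg <- imgs[seq_len(n_targets)]
    targets[tr, ] <- tg
    # 6 target presentations (the targets, repeated) and 6 distractors,
    # "fairly distributed": an equal split within every trial
    shown_t <- rep(tg, length.out = items_per_trial - n_distract)
    shown_d <- imgs[n_targets + seq_len(n_distract)]
    ord <- sample.int(items_per_trial)
    image <- c(shown_t, shown_d)[ord]
    is_target <- c(rep(TRUE, length(shown_t)),
                   rep(FALSE, n_distract))[ord]
    jit <- stats::runif(items_per_trial, jitter_range[1], jitter_range[2])
    onset <- encoding_s + gap_s + cumsum(jit + 1) - 1
    items[[tr]] <- data.frame(trial = tr, block = trials$block[tr],
                              item = seq_len(items_per_trial),
                              image = image, is_target = is_target,
                              onset_s = onset, jitter_s = jit,
                              stringsAsFactors = FALSE)
  }
  trials$target_1 <- targets[, 1]
  trials$target_2 <- targets[, 2]
  structure(list(trials = trials, items = do.call(rbind, items)),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule> %d trials (%d blocks), %d test items (%d targets)\n",
              nrow(x$trials), length(unique(x$trials$block)),
              nrow(x$items), sum(x$items$is_target)))
  invisible(x)
}

#' Simulate keypress responses to a task schedule
#'
#' Correctness is Bernoulli per test item (separate probabilities for
#' target and non-target items); reaction times are lognormal with the
#' requested mean and SD in milliseconds, with separate location/scale for
#' correct target, correct non-target, incorrect target and incorrect
#' non-target responses, truncated to the 1-s response window plus a
#' 500-ms grace period. A `p_miss` fraction of items receives no response.
#'
#' @param schedule a `task_schedule`.
#' @param params list with `p_correct_target`, `p_correct_nontarget`,
#'   `rt_mean_ms`, `rt_sd_ms` (correct-target RT), `rt_shift_nontarget_ms`
#'   (added to the correct non-target mean), `rt_mean_incorrect_target_ms`,
#'   `rt_sd_incorrect_target_ms`, `rt_mean_incorrect_nontarget_ms`,
#'   `rt_sd_incorrect_nontarget_ms`, `p_miss`. Missing entries take the
#'   defaults of [behavior_params()].
#' @param seed integer seed.
#' @return A `response_log` data frame: one row per presented item with
#'   `trial`, `item`, `is_target`, `response` (`match` / `nonmatch` /
#'   `none`), `correct`, `rt_ms`.
#' @export
simulate_responses <- function(schedule, params = behavior_params(),
                               seed = 1) {
  p <- utils::modifyList(behavior_params(), params)
  stopifnot(p$p_correct_target >= 0, p$p_correct_target <= 1,
            p$p_correct_nontarget >= 0, p$p_correct_nontarget <= 1)
  set.seed(seed)
  it <- schedule$items
  n <- nrow(it)
  p_correct <- ifelse(it$is_target, p$p_correct_target,
                      p$p_correct_nontarget)
  correct <- stats::runif(n) < p_correct
  miss <- stats::runif(n) < p$p_miss
  response <- ifelse(miss, "none",
                     ifelse(correct == it$is_target, "match", "nonmatch"))
  correct[miss] <- FALSE
  rt_mean <- ifelse(it$is_target,
                    ifelse(correct, p$rt_mean_ms,
                           p$rt_mean_incorrect_target_ms),
                    ifelse(correct, p$rt_mean_ms + p$rt_shift_nontarget_ms,
                           p$rt_mean_incorrect_nontarget_ms))
  rt_sd <- ifelse(it$is_target,
                  ifelse(correct, p$rt_sd_ms, p$rt_sd_incorrect_target_ms),
                  ifelse(correct, p$rt_sd_nontarget_ms,
                         p$rt_sd_incorrect_nontarget_ms))
  sdlog <- sqrt(log(1 + rt_sd^2 / rt_mean^2))
  meanlog <- log(rt_mean) - sdlog^2 / 2
  rt <- pmin(stats::rlnorm(n, meanlog, sdlog), 1500)
  rt[miss] <- NA_real_
  out <- data.frame(trial = it$trial, item = it$item,
                    is_target = it$is_target, response = response,
                    correct = correct, rt_ms = rt,
                    stringsAsFactors = FALSE)
  class(out) <- c("response_log", class(out))
  out
}

#' Default behavioral simulation parameters
#'
#' Centered on the cohort-level values the simulated study reproduces:
#' 91.56% / 91.93% correct for target / non-target items, correct RT
#' 673 (51) ms to targets and 698 (48) ms to non-targets, incorrect RT
#' 649 (85) ms / 715 (118) ms.
#'
#' @return Named list of parameters for [simulate_responses()].
#' @export
behavior_params <- function() {
  list(p_correct_target = 0.9156, p_correct_nontarget = 0.9193,
       rt_mean_ms = 673, rt_sd_ms = 51,
       rt_shift_nontarget_ms = 25, rt_sd_nontarget_ms = 48,
       rt_mean_incorrect_target_ms = 649, rt_sd_incorrect_target_ms = 85,
       rt_mean_incorrect_nontarget_ms = 715,
       rt_sd_incorrect_nontarget_ms = 118,
       p_miss = 0)
}

#' Score a response log against its schedule
#'
#' Accuracy is 100 x correct / presented per stimulus type; non-responses
#' count as incorrect and contribute no reaction time. Reaction-time means
#' are split by correctness x stimulus type; a cell with no trials is
#' reported as `NA`.
#'
#' @param schedule the `task_schedule` the log was recorded against.
#' @param log a `response_log` from [simulate_responses()] (or real data in
#'   the same shape).
#' @return One-row data frame (`behavior_summary`): accuracy_target_pct,
#'   accuracy_nontarget_pct, accuracy_pct, mean_rt_correct_target_ms,
#'   mean_rt_correct_nontarget_ms, mean_rt_incorrect_target_ms,
#'   mean_rt_incorrect_nontarget_ms, mean_rt_ms.
#' @export
score_responses <- function(schedule, log) {
  if (nrow(log) != nrow(schedule$items) ||
      !all(log$trial == schedule$items$trial) ||
      !all(log$item == schedule$items$item))
    stop("response log does not pair with the schedule (one row per item)")
  tgt <- log$is_target
  acc <- function(sel) 100 * sum(log$correct[sel]) / sum(sel)
  mrt <- function(sel) {
    v <- log$rt_ms[sel & log$response != "none"]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  data.frame(
    accuracy_target_pct = acc(tgt),
    accuracy_nontarget_pct = acc(!tgt),
    accuracy_pct = acc(rep(TRUE, nrow(log))),
    mean_rt_correct_target_ms = mrt(tgt & log$correct),
    mean_rt_correct_nontarget_ms = mrt(!tgt & log$correct),
    mean_rt_incorrect_target_ms = mrt(tgt & !log$correct),
    mean_rt_incorrect_nontarget_ms = mrt(!tgt & !log$correct),
    mean_rt_ms = mrt(log$correct))
}

#' Kruskal-Wallis rank test
#'
#' The non-parametric k-group test on ranks,
#' `H = 12 / (N (N + 1)) * sum n_i (Rbar_i - (N + 1) / 2)^2` with the
#' midrank ties correction, referred to a chi-square distribution with
#' k - 1 degrees of freedom. Computed via [stats::kruskal.test()].
#'
#' @param ... two or more numeric vectors, or a single list of them.
#' @return List with `H`, `df`, `p`. Identical values in all groups give
#'   `H = 0`, `p = 1`.
#' @examples
#' kruskal_wallis(c(1, 2, 3), c(4, 5, 6))$H  # 3.857...
#' @export
kruskal_wallis <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 1))
    stop("each group needs at least one value")
  values <- unlist(groups)
  if (length(values) < 3) stop("need at least 3 values in total")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Simulate and score a behavioral cohort
#'
#' Builds one schedule and one response log per subject and scores them,
#' producing the per-subject behavior summary table.
#'
#' @param n_subjects number of subjects.
#' @param params see [simulate_responses()].
#' @param seed integer seed (per-subject streams are derived from it).
#' @return Data frame with a `subject` column plus the
#'   [score_responses()] summary columns.
#' @export
simulate_behavior_cohort <- function(n_subjects = 43,
                                     params = behavior_params(), seed = 1) {
  rows <- lapply(seq_len(n_subjects), function(i) {
    sched <- build_task_schedule(seed = derive_seed(seed, i, 21))
    log <- simulate_responses(sched, params,
                              seed = derive_seed(seed, i, 22))
    cbind(data.frame(subject = sprintf("S%02d", i),
                     stringsAsFactors = FALSE),
          score_responses(sched, log))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
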
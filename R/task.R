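#' Generate an Executive reaction-time test session
#'
#' Builds the trial sequence of a Go/NoGo session: a number of practice
#' blocks followed by test blocks. Each block holds 64 trials crossing
#' condition (32 Go / 32 NoGo) with distractor valence (16 emotional /
#' 16 neutral per condition) and triangle orientation, in seeded random
#' order. The response rule (which traffic-light colour is the Go signal)
#' alternates between consecutive blocks, and the stimulator metadata flag
#' is ON for the first half of each block and OFF for the second half.
#'
#' @param seed Integer seed for the trial-order permutation; `NULL` uses the
#'   current RNG state.
#' @param n_practice,n_test Number of practice and test blocks (default 4 + 4).
#' @return A data frame with one row per trial and columns `block`,
#'   `is_practice`, `trial`, `triangle` (`"up"`/`"down"`), `light`
#'   (`"green"`/`"red"`), `go_rule` (the block's Go colour), `condition`
#'   (`"Go"` iff `light == go_rule`), `distractor` (`"emotional"`/`"neutral"`),
#'   and `stimulator` (`"ON"`/`"OFF"`).
#' @examples
#' sess <- generate_session(seed = 1)
#' table(sess$block, sess$condition)
#' @export
generate_session <- function(seed = NULL, n_practice = 4, n_test = 4) {
  stopifnot(n_practice >= 0, n_test >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- n_practice + n_test
  if (n_blocks == 0) {
    return(empty_session())
  }
  cells <- expand.grid(
    condition  = c("Go", "NoGo"),
    distractor = c("emotional", "neutral"),
    triangle   = c("up", "down"),
    rep        = seq_len(8),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("condition", "distractor", "triangle")]
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    ord <- sample.int(64L)
    blk <- cells[ord, , drop = FALSE]
    go_rule <- if (b %% 2L == 1L) "green" else "red"
    other   <- if (go_rule == "green") "red" else "green"
    blocks[[b]] <- data.frame(
      block       = b,
      is_practice = b <= n_practice,
      trial       = seq_len(64L),
      triangle    = blk$triangle,
      light       = ifelse(blk$condition == "Go", go_rule, other),
      go_rule     = go_rule,
      condition   = blk$condition,
      distractor  = blk$distractor,
      stimulator  = rep(c("ON", "OFF"), each = 32L),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

empty_session <- function() {
  data.frame(block = integer(), is_practice = logical(), trial = integer(),
             triangle = character(), light = character(), go_rule = character(),
             condition = character(), distractor = character(),
             stimulator = character(), stringsAsFactors = FALSE)
}

#' Classify behavioural responses against the trial design
#'
#' Applies the four outcome dichotomisations used in the error analyses.
#' A Go trial is correct when the button matches the triangle orientation
#' shown at trial onset (`up` -> up button, `down` -> down button),
#' incorrect when the wrong button is pressed, and a miss when no button is
#' pressed. Any press on a NoGo trial is a commission error; withholding is
#' correct. `class_total` is `"error"` iff the trial is an incorrect press,
#' a miss, or a commission.
#'
#' Classification is a pure function of its inputs: the same trial/response
#' pair always yields the same outcome.
#'
#' @param trials Data frame of trials as from [generate_session()].
#' @param responses Data frame with columns `pressed` (logical), `button`
#'   (`"up"`, `"down"`, or `"none"`), and `rt_ms` (`NA` when not pressed),
#'   row-aligned with `trials`.
#' @return `trials` with the response columns plus `outcome` (one of
#'   `"correct"`, `"incorrect"`, `"miss"`, `"commission"`) and the four
#'   dichotomisation columns `class_total`, `class_incorrect`, `class_miss`,
#'   `class_commission`.
#' @export
classify_outcomes <- function(trials, responses) {
  stopifnot(nrow(trials) == nrow(responses),
            all(c("pressed", "button") %in% names(responses)))
  if (any(responses$pressed != (responses$button != "none")))
    stop("'button' must be \"none\" exactly when 'pressed' is FALSE")
  go <- trials$condition == "Go"
  match_btn <- (trials$triangle == "up" & responses$button == "up") |
    (trials$triangle == "down" & responses$button == "down")
  outcome <- character(nrow(trials))
  outcome[go  & responses$pressed & match_btn]  <- "correct"
  outcome[go  & responses$pressed & !match_btn] <- "incorrect"
  outcome[go  & !responses$pressed]             <- "miss"
  outcome[!go & responses$pressed]              <- "commission"
  outcome[!go & !responses$pressed]             <- "correct"
  out <- cbind(trials, responses)
  out$outcome          <- outcome
  out$class_total      <- ifelse(outcome == "correct", "correct", "error")
  out$class_incorrect  <- ifelse(outcome == "incorrect", "incorrect", "other")
  out$class_miss       <- ifelse(outcome == "miss", "miss", "other")
  out$class_commission <- ifelse(go, "not_applicable",
                                 ifelse(outcome == "commission",
                                        "commission_error", "correct"))
  out
}

#' @rdname classify_outcomes
#' @param trial,response Single-row versions of `trials` / `responses`.
#' @export
classify_response <- function(trial, response) {
  classify_outcomes(as.data.frame(trial), as.data.frame(response))
}

#' Summarise behavioural performance
#'
#' Computes, per subject, the median and IQR of reaction times on correct Go
#' trials and error percentages by type. Denominators follow the
#' dichotomisation domains: incorrect and missing responses as a percentage
#' of Go trials, commission errors as a percentage of NoGo trials, total
#' errors over all trials. With several subjects, across-subject medians and
#' IQRs are also reported. Practice blocks are excluded by default.
#'
#' @param outcomes Classified trials from [classify_outcomes()]; may contain
#'   a `subject` column (a single implicit subject is assumed otherwise).
#' @param practice_excluded Drop practice-block trials first (default `TRUE`).
#' @return An object of class `behavior_summary`: a list with `per_subject`
#'   (one row per subject) and `group` (across-subject median/IQR per metric).
#' @export
summarize_behavior <- function(outcomes, practice_excluded = TRUE) {
  if (practice_excluded && "is_practice" %in% names(outcomes))
    outcomes <- outcomes[!outcomes$is_practice, , drop = FALSE]
  if (nrow(outcomes) == 0)
    stop("no trials left to summarise after practice exclusion")
  if (!"subject" %in% names(outcomes)) outcomes$subject <- "s1"
  per <- lapply(split(outcomes, outcomes$subject), function(d) {
    go <- d$condition == "Go"
    rts <- d$rt_ms[go & d$outcome == "correct"]
    data.frame(
      subject        = d$subject[1],
      n_trials       = nrow(d),
      median_rt_ms   = if (length(rts)) median(rts) else NA_real_,
      iqr_rt_ms      = if (length(rts)) IQR(rts) else NA_real_,
      pct_total      = 100 * mean(d$class_total == "error"),
      pct_incorrect  = 100 * mean(d$outcome[go] == "incorrect"),
      pct_miss       = 100 * mean(d$outcome[go] == "miss"),
      pct_commission = 100 * mean(d$outcome[!go] == "commission"),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  metrics <- c("median_rt_ms", "pct_total", "pct_incorrect",
               "pct_miss", "pct_commission")
  grp <- data.frame(
    metric = metrics,
    median = vapply(metrics, function(m) median(per[[m]], na.rm = TRUE), 0),
    iqr    = vapply(metrics, function(m) IQR(per[[m]], na.rm = TRUE), 0),
    stringsAsFactors = FALSE
  )
  rownames(grp) <- NULL
  structure(list(per_subject = per, group = grp), class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("Behavioural summary over", nrow(x$per_subject), "subject(s)\n")
  print(x$group, row.names = FALSE, digits = 4)
  invisible(x)
}
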
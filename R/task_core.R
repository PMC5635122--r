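# Domain objects and task plumbing: item pairs, bid profiles, preference
# quantities (delta_v, rho), the pseudorandomized trial schedule, and
# delimited-text dataset I/O.

#' Construct an item-pair table
#'
#' @param pair_id character or integer vector of unique pair identifiers.
#' @param item_a items designated correct (the partner's choice).
#' @param item_b the alternatives.
#' @return data.frame with columns `pair`, `item_a`, `item_b`.
#' @export
item_pairs <- function(pair_id, item_a, item_b) {
  pair_id <- as.character(pair_id)
  item_a <- as.character(item_a)
  item_b <- as.character(item_b)
  if (anyDuplicated(pair_id)) stop("pair ids must be unique")
  if (any(item_a == item_b)) stop("item_a and item_b must differ within a pair")
  data.frame(pair = pair_id, item_a = item_a, item_b = item_b,
             stringsAsFactors = FALSE)
}

#' Construct a bid-profile table
#'
#' One row per (participant, item); bids are willingness-to-pay in pounds,
#' bounded to [0, 3].
#'
#' @param participant participant id vector.
#' @param item item id vector.
#' @param bid_gbp numeric bids in pounds.
#' @return data.frame with columns `participant`, `item`, `bid_gbp`.
#' @export
bid_profiles <- function(participant, item, bid_gbp) {
  if (any(bid_gbp < 0 | bid_gbp > 3)) {
    bad <- which(bid_gbp < 0 | bid_gbp > 3)[1]
    stop(sprintf("bid out of [0, 3] at row %d (%.2f)", bad, bid_gbp[bad]))
  }
  df <- data.frame(participant = as.character(participant),
                   item = as.character(item),
                   bid_gbp = as.numeric(bid_gbp), stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("participant", "item")]))
    stop("duplicate (participant, item) bid")
  df
}

bid_lookup <- function(bids, participant, item) {
  hit <- bids$participant == participant & bids$item == item
  if (!any(hit)) {
    stop(sprintf("no bid for item '%s' (participant '%s')", item, participant))
  }
  bids$bid_gbp[which(hit)[1]]
}

#' Preference congruence for a pair
#'
#' The bid difference delta_v: the participant's bid for the correct item
#' (`item_a`) minus the bid for the incorrect item (`item_b`). Positive
#' values mean the participant's own preference agrees with the correct
#' answer.
#'
#' @param bids bid-profile data.frame (see [bid_profiles()]).
#' @param pair one row of an [item_pairs()] table (or a list with
#'   `item_a`, `item_b`).
#' @param participant participant id.
#' @return numeric delta_v in pounds, in [-3, 3].
#' @export
compute_delta_v <- function(bids, pair, participant) {
  bid_lookup(bids, participant, pair$item_a) -
    bid_lookup(bids, participant, pair$item_b)
}

#' Relative item popularity
#'
#' rho: the fraction of *other* participants who bid more for the correct
#' item than its alternative, minus 0.5. A rho of 0.25 means 75% of others
#' preferred the correct item; -0.25 means 25% did. Tied bids contribute
#' half a count, which keeps rho antisymmetric under swapping the items.
#'
#' @param bids bid-profile data.frame covering the reference population.
#' @param pair one row of an [item_pairs()] table.
#' @param exclude participant id excluded from the reference population
#'   (the learner herself).
#' @return numeric rho in [-0.5, 0.5].
#' @export
compute_popularity <- function(bids, pair, exclude) {
  others <- setdiff(unique(bids$participant), exclude)
  if (length(others) == 0) stop("empty reference population for popularity")
  prefers <- vapply(others, function(p) {
    da <- bid_lookup(bids, p, pair$item_a) - bid_lookup(bids, p, pair$item_b)
    if (da > 0) 1 else if (da < 0) 0 else 0.5
  }, numeric(1))
  mean(prefers) - 0.5
}

#' Preference-pair table for one learner
#'
#' Convenience wrapper: delta_v and rho for every pair, for one participant
#' against a reference population.
#'
#' @inheritParams compute_popularity
#' @param pairs full [item_pairs()] table.
#' @param participant learner id.
#' @return data.frame `pair`, `delta_v`, `rho`.
#' @export
preference_pairs <- function(bids, pairs, participant) {
  dv <- vapply(seq_len(nrow(pairs)), function(i)
    compute_delta_v(bids, pairs[i, ], participant), numeric(1))
  rho <- vapply(seq_len(nrow(pairs)), function(i)
    compute_popularity(bids, pairs[i, ], exclude = participant), numeric(1))
  data.frame(pair = pairs$pair, delta_v = dv, rho = rho,
             stringsAsFactors = FALSE)
}

# draw a sequence of pair slots with no immediate repeats: sequential
# sampling proportional to remaining counts, restarting on dead ends
shuffle_no_repeat <- function(counts, prev = "", max_restarts = 200L) {
  ids <- names(counts)
  total <- sum(counts)
  for (attempt in seq_len(max_restarts)) {
    rem <- counts
    out <- character(total)
    last <- prev
    ok <- TRUE
    for (i in seq_len(total)) {
      avail <- ids[rem > 0 & ids != last]
      if (length(avail) == 0) { ok <- FALSE; break }
      pick <- if (length(avail) == 1) avail else
        sample(avail, 1, prob = rem[avail])
      out[i] <- pick
      rem[pick] <- rem[pick] - 1
      last <- pick
    }
    if (ok) return(out)
  }
  stop("could not build a no-immediate-repeat sequence; constraints too tight")
}

#' Build a pseudorandomized trial schedule
#'
#' 600 trials: 3 blocks of 200, each of the 20 pairs shown 10 times per
#' block, never twice in a row (including across block boundaries), each
#' item on each side of the screen 5 times per block. Feedback is veridical
#' with probability `p_fb`; under the default `"balanced"` dialect exactly
#' `round(10 * p_fb)` of each pair's 10 within-block presentations are
#' veridical, in shuffled order (matching both the stated 80% marginal rate
#' and the pseudorandomized presentation); `"bernoulli"` draws feedback
#' accuracy i.i.d. per trial.
#'
#' @param pairs [item_pairs()] table (any number of pairs; the reference
#'   task uses 20).
#' @param presentations presentations of each pair per block (default 10).
#' @param blocks number of blocks (default 3).
#' @param p_fb feedback reliability in (0.5, 1].
#' @param feedback `"balanced"` or `"bernoulli"`.
#' @param seed optional integer; when given the schedule is reproducible.
#' @return data.frame `trial`, `block`, `pair`, `n` (presentation index
#'   within pair), `side_of_a` ("left"/"right"), `feedback_veridical`.
#' @export
build_schedule <- function(pairs, presentations = 10L, blocks = 3L,
                           p_fb = 0.8, feedback = c("balanced", "bernoulli"),
                           seed = NULL) {
  feedback <- match.arg(feedback)
  if (!is.null(seed)) set.seed(seed)
  if (p_fb <= 0.5 || p_fb > 1) stop("p_fb must be in (0.5, 1]")
  npair <- nrow(pairs)
  if (npair < 2) stop("need at least 2 pairs")
  if (presentations %% 2 != 0)
    stop("presentations per block must be even for left/right counterbalancing")
  n_ver <- round(presentations * p_fb)

  blocks_out <- vector("list", blocks)
  prev <- ""
  for (b in seq_len(blocks)) {
    counts <- setNames(rep(as.integer(presentations), npair), pairs$pair)
    seq_pairs <- shuffle_no_repeat(counts, prev = prev)
    prev <- seq_pairs[length(seq_pairs)]
    # per-pair within-block side and feedback assignments
    side <- character(length(seq_pairs))
    ver <- logical(length(seq_pairs))
    for (pid in pairs$pair) {
      idx <- which(seq_pairs == pid)
      side[idx] <- sample(rep(c("left", "right"), presentations / 2))
      ver[idx] <- if (feedback == "balanced") {
        sample(c(rep(TRUE, n_ver), rep(FALSE, presentations - n_ver)))
      } else {
        runif(presentations) < p_fb
      }
    }
    blocks_out[[b]] <- data.frame(block = b, pair = seq_pairs,
                                  side_of_a = side, feedback_veridical = ver,
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks_out)
  out$trial <- seq_len(nrow(out))
  out$n <- as.integer(ave(seq_len(nrow(out)), out$pair, FUN = seq_along))
  out[, c("trial", "block", "pair", "n", "side_of_a", "feedback_veridical")]
}

#' Validate a trial-schedule data.frame
#'
#' Checks the pseudorandomization invariants; errors with an informative
#' message naming the first violation.
#'
#' @param schedule output of [build_schedule()].
#' @param presentations,blocks,p_fb,feedback the constraints to check against.
#' @return invisibly TRUE.
#' @export
validate_schedule <- function(schedule, presentations = 10L, blocks = 3L,
                              p_fb = 0.8, feedback = "balanced") {
  if (any(schedule$pair[-1] == schedule$pair[-nrow(schedule)]))
    stop("pair repeated on consecutive trials")
  per_block <- table(schedule$block, schedule$pair)
  if (any(per_block != presentations))
    stop("a pair is not shown the required number of times in some block")
  sides <- table(schedule$block, schedule$pair, schedule$side_of_a)
  if (any(sides != presentations / 2))
    stop("left/right counterbalancing violated")
  if (identical(feedback, "balanced")) {
    nv <- tapply(schedule$feedback_veridical,
                 list(schedule$block, schedule$pair), sum)
    if (any(nv != round(presentations * p_fb)))
      stop("per-pair per-block veridical feedback count violated")
  }
  for (pid in unique(schedule$pair)) {
    nn <- schedule$n[schedule$pair == pid]
    if (!all(nn == seq_along(nn))) stop("presentation index n not sequential")
  }
  invisible(TRUE)
}

#' Write a dataset bundle to a directory
#'
#' Three CSV files: `bids.csv` (`participant,item,bid_gbp`), `pairs.csv`
#' (`pair,item_a,item_b`) and `trials.csv`
#' (`participant,pair,n,block,side_of_a,response,rt_s,feedback_item`).
#'
#' @param dataset list with elements `bids`, `pairs`, `trials`.
#' @param dir output directory (created if missing).
#' @return invisibly `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(dataset$bids, file.path(dir, "bids.csv"), row.names = FALSE)
  write.csv(dataset$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  write.csv(dataset$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read and validate a dataset bundle
#'
#' Inverse of [write_dataset()]. Validation failures report the file, the
#' offending row and the violated rule.
#'
#' @param dir directory containing `bids.csv`, `pairs.csv`, `trials.csv`.
#' @return list with `bids`, `pairs`, `trials` data.frames.
#' @export
read_dataset <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing file: %s", p))
    read.csv(p, stringsAsFactors = FALSE, colClasses = NA)
  }
  bids <- need("bids.csv"); pairs <- need("pairs.csv"); trials <- need("trials.csv")
  check_cols <- function(df, cols, fname) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s: missing column(s) %s", fname, paste(miss, collapse = ", ")))
  }
  check_cols(bids, c("participant", "item", "bid_gbp"), "bids.csv")
  check_cols(pairs, c("pair", "item_a", "item_b"), "pairs.csv")
  check_cols(trials, c("participant", "pair", "n", "block", "side_of_a",
                       "response", "rt_s", "feedback_item"), "trials.csv")
  for (col in c("participant", "item")) bids[[col]] <- as.character(bids[[col]])
  for (col in c("pair", "item_a", "item_b")) pairs[[col]] <- as.character(pairs[[col]])
  for (col in c("participant", "pair", "side_of_a", "response", "feedback_item"))
    trials[[col]] <- as.character(trials[[col]])

  bad <- which(bids$bid_gbp < 0 | bids$bid_gbp > 3)
  if (length(bad))
    stop(sprintf("bids.csv row %d: bid %.2f outside [0, 3]", bad[1], bids$bid_gbp[bad[1]]))
  bad <- which(trials$rt_s <= 0)
  if (length(bad))
    stop(sprintf("trials.csv row %d: rt_s must be positive", bad[1]))
  bad <- which(!(trials$response %in% c(pairs$item_a, pairs$item_b)))
  if (length(bad))
    stop(sprintf("trials.csv row %d: response '%s' is not an item of any pair",
                 bad[1], trials$response[bad[1]]))
  # n strictly sequential per (participant, pair)
  key <- interaction(trials$participant, trials$pair, drop = TRUE)
  for (k in levels(key)) {
    nn <- trials$n[key == k]
    if (!all(nn == seq_along(nn)))
      stop(sprintf("trials.csv: presentation index not sequential for %s", k))
  }
  list(bids = bids, pairs = pairs, trials = trials)
}
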
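#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

test_conditions <- function() {
  c("match", "mismatch", "old_new", "new_old", "new_new")
}

#' Generate the item-context association study design
#'
#' Builds the encoding and test lists of the scene-object association
#' paradigm.  During encoding, each scene is studied as a sequence of 5
#' objects (encoding positions 1-5), giving `5 * n_scenes` encoding trials.
#' At test, the old objects reappear on their original scene (match), on a
#' different old scene (mismatch) or on a new scene (old-new), and new
#' objects appear on old (new-old) or new (new-new) scenes, with condition
#' sizes `2n / 2n / n / 2n / n`.
#'
#' Three ordering constraints are enforced on the test list:
#' \enumerate{
#'   \item per scene, exactly 2 of its objects are tested in the match
#'     condition, 2 in mismatch and 1 in old-new, with encoding positions
#'     counterbalanced across conditions (exact balance whenever `n_scenes`
#'     is divisible by 5);
#'   \item no more than 3 consecutive test trials share a condition;
#'   \item no scene is displayed in two consecutive test trials.
#' }
#' The ordering is found by randomized greedy construction with restarts; if
#' no admissible ordering is found within `max_retries` restarts an error is
#' raised rather than returning a list violating the constraints.
#'
#' @param n_scenes Number of encoding scenes (>= 1).  The study-scale design
#'   uses 50 scenes (250 encoding trials, 400 test trials).
#' @param seed Optional integer seed; the function leaves the global RNG
#'   state untouched.
#' @param max_retries Restart cap for the constrained ordering search.
#' @return An object of class `"study_design"`: a list with `scenes`,
#'   `new_scenes`, `encoding` (data frame: trial, scene, object, position)
#'   and `test` (data frame: trial, object, scene, condition, item_old,
#'   position).
#' @export
#' @examples
#' d <- generate_design(5, seed = 1)
#' table(d$test$condition)
generate_design <- function(n_scenes, seed = NULL, max_retries = 1000) {
  stopifnot(is.numeric(n_scenes), length(n_scenes) == 1, n_scenes >= 1)
  n <- as.integer(n_scenes)
  with_seed(seed, {
    scenes <- sprintf("scene_%03d", seq_len(n))
    new_scenes <- sprintf("scene_%03d", n + seq_len(2L * n))
    objects <- sample(sprintf("obj_%04d", seq_len(8L * n)))
    old_obj <- objects[seq_len(5L * n)]
    new_obj <- objects[5L * n + seq_len(3L * n)]

    # encoding: random scene order, 5 objects per scene in serial positions 1-5
    scene_order <- sample(scenes)
    encoding <- data.frame(
      trial = seq_len(5L * n),
      scene = rep(scene_order, each = 5L),
      object = old_obj,
      position = rep(1:5, n),
      stringsAsFactors = FALSE
    )

    # per-scene assignment of encoding positions to old-object test conditions;
    # rotations of the base pattern are balanced within blocks of 5 scenes so
    # every position feeds every condition equally when n is divisible by 5
    base <- c("match", "match", "mismatch", "mismatch", "old_new")
    shifts <- integer(n)
    full_blocks <- n %/% 5L
    for (b in seq_len(full_blocks)) shifts[(b - 1L) * 5L + 1:5] <- sample(0:4)
    if (n %% 5L > 0L) {
      tail_idx <- full_blocks * 5L + seq_len(n %% 5L)
      shifts[tail_idx] <- sample(0:4, length(tail_idx), replace = TRUE)
    }

    old_rows <- vector("list", n)
    for (i in seq_len(n)) {
      sc <- scene_order[i]
      enc_i <- encoding[encoding$scene == sc, ]
      cond <- base[((enc_i$position - 1L + shifts[i]) %% 5L) + 1L]
      # displayed scene: match -> own; mismatch -> another old scene (cyclic
      # shifts keep hosting balanced at 2 mismatch objects per old scene);
      # old-new -> a dedicated new scene
      disp <- character(5L)
      disp[cond == "match"] <- sc
      mm_shift <- if (n > 2L) c(1L, 2L) else c(1L, 1L)
      if (n == 1L) mm_shift <- c(0L, 0L)  # degenerate: only one old scene exists
      disp[cond == "mismatch"] <- scene_order[((i - 1L + mm_shift) %% n) + 1L]
      disp[cond == "old_new"] <- new_scenes[i]
      old_rows[[i]] <- data.frame(
        object = enc_i$object, scene = disp, condition = cond,
        item_old = TRUE, position = enc_i$position, stringsAsFactors = FALSE
      )
    }
    old_rows <- do.call(rbind, old_rows)

    new_rows <- data.frame(
      object = new_obj,
      scene = c(rep(scene_order, each = 2L), new_scenes[n + seq_len(n)]),
      condition = rep(c("new_old", "new_new"), c(2L * n, n)),
      item_old = FALSE, position = NA_integer_, stringsAsFactors = FALSE
    )
    trials <- rbind(old_rows, new_rows)

    ord <- order_test_trials(trials, max_retries = max_retries)
    test <- trials[ord, ]
    test$trial <- seq_len(nrow(test))
    rownames(test) <- NULL
    test <- test[, c("trial", "object", "scene", "condition", "item_old", "position")]

    out <- structure(
      list(scenes = scenes, new_scenes = new_scenes,
           encoding = encoding, test = test),
      class = "study_design", n_scenes = n
    )
    validate_design(out)
    out
  })
}

# randomized greedy sequencing with restarts; returns a permutation of rows
#' @noRd
order_test_trials <- function(trials, max_retries = 1000, max_run = 3L) {
  n <- nrow(trials)
  # the no-consecutive-scene rule is infeasible when one scene fills more than
  # half the list (only possible for degenerate one-scene designs)
  scene_rule <- max(table(trials$scene)) <= (n + 1L) %/% 2L
  if (!scene_rule)
    warning("scene-repeat constraint infeasible for this design size; dropped")
  for (attempt in seq_len(max_retries)) {
    remaining <- seq_len(n)
    ord <- integer(n)
    prev_scene <- ""
    run_cond <- ""
    run_len <- 0L
    ok <- TRUE
    for (k in seq_len(n)) {
      cand <- if (scene_rule) remaining[trials$scene[remaining] != prev_scene]
              else remaining
      if (run_len >= max_run)
        cand <- cand[trials$condition[cand] != run_cond]
      if (length(cand) == 0L) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      ord[k] <- pick
      remaining <- remaining[remaining != pick]
      prev_scene <- trials$scene[pick]
      if (identical(trials$condition[pick], run_cond)) {
        run_len <- run_len + 1L
      } else {
        run_cond <- trials$condition[pick]
        run_len <- 1L
      }
    }
    if (ok) return(ord)
  }
  stop("could not order test trials under the run-length and scene-repeat ",
       "constraints within ", max_retries, " restarts")
}

#' @noRd
longest_run <- function(x) {
  if (length(x) == 0L) return(0L)
  max(rle(as.character(x))$lengths)
}

#' Validate a study design against its structural invariants
#'
#' Checks encoding/test counts, the per-scene condition assignment, the
#' mismatch-scene rule and the two ordering constraints; stops on the first
#' violation.
#'
#' @param design A `"study_design"` object.
#' @return `design`, invisibly.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  n <- attr(design, "n_scenes")
  enc <- design$encoding
  tst <- design$test
  if (nrow(enc) != 5L * n) stop("encoding trial count != 5 * n_scenes")
  if (!all(table(enc$scene) == 5L)) stop("every scene must have 5 encoding objects")
  cond_n <- table(factor(tst$condition, levels = test_conditions()))
  want <- c(match = 2L * n, mismatch = 2L * n, old_new = n,
            new_old = 2L * n, new_new = n)
  if (!all(cond_n[names(want)] == want)) stop("test condition counts are wrong")
  # per-scene object assignment 2/2/1
  old_tst <- tst[tst$item_old, ]
  src <- enc$scene[match(old_tst$object, enc$object)]
  tab <- table(src, factor(old_tst$condition, levels = c("match", "mismatch", "old_new")))
  if (!all(tab[, "match"] == 2L) || !all(tab[, "mismatch"] == 2L) ||
      !all(tab[, "old_new"] == 1L))
    stop("per-scene condition assignment must be 2 match / 2 mismatch / 1 old-new")
  # mismatch displayed on an old scene different from the source scene
  mm <- old_tst$condition == "mismatch"
  if (!all(old_tst$scene[mm] %in% design$scenes))
    stop("mismatch trials must display old scenes")
  if (n > 1L && any(old_tst$scene[mm] == src[mm]))
    stop("mismatch trials must display a different old scene")
  if (longest_run(tst$condition) > 3L)
    stop("more than 3 consecutive test trials share a condition")
  scene_rule_feasible <- max(table(tst$scene)) <= (nrow(tst) + 1L) %/% 2L
  if (scene_rule_feasible && any(tst$scene[-1L] == tst$scene[-nrow(tst)]))
    stop("a scene is displayed in consecutive test trials")
  invisible(design)
}

#' @export
print.study_design <- function(x, ...) {
  n <- attr(x, "n_scenes")
  cat("Item-context study design:", n, "scenes\n")
  cat("  encoding trials:", nrow(x$encoding), "\n")
  cat("  test trials:    ", nrow(x$test), "\n")
  print(table(x$test$condition)[test_conditions()])
  invisible(x)
}
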
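# the end-to-end active-learning driver, evaluation curves, strategy
# comparison and reporting.

#' Experiment configuration
#'
#' @param strategy one of `BDalpha, Dalpha, BDalpha_CE, HBDalpha, HDalpha,
#'   HB, H, H_dropout, rand, uniform`.
#' @param alpha Dice-smoothing weight, default 0.5.
#' @param epsilon boundary-statistics prior constant, default 0.01.
#' @param mc_samples Monte Carlo dropout samples for `H_dropout`, default 20.
#' @param dropout_rate test-time dropout probability of the backbone,
#'   default 0.5.
#' @param target_dice stop once mean evaluation Dice reaches this value.
#' @param budget_frac stop once cumulative cost reaches this fraction of
#'   the stack's total annotation cost.
#' @param max_iter cap on the number of queries.
#' @param foreground_only average evaluation Dice over foreground classes
#'   only (background excluded), default `TRUE`.
#' @param train a [train_config()].
#' @param seed master seed; every stochastic component (bootstrap draw,
#'   training shuffles, baseline selections, MC dropout) derives its own
#'   sub-seed from it, which makes runs reproducible and resumable.
#' @return An `experiment_config` list (at least one stopping rule is
#'   required).
#' @export
experiment_config <- function(strategy = "BDalpha", alpha = 0.5,
                              epsilon = 0.01, mc_samples = 20L,
                              dropout_rate = 0.5,
                              target_dice = NULL, budget_frac = NULL,
                              max_iter = NULL, foreground_only = TRUE,
                              train = train_config(), seed = 1L) {
  if (!strategy %in% strategy_names) stop("unknown strategy: ", strategy)
  if (is.null(target_dice) && is.null(budget_frac) && is.null(max_iter))
    stop("set at least one stopping criterion")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(strategy = strategy, alpha = alpha, epsilon = epsilon,
                 mc_samples = as.integer(mc_samples),
                 dropout_rate = dropout_rate,
                 target_dice = target_dice, budget_frac = budget_frac,
                 max_iter = max_iter, foreground_only = foreground_only,
                 train = train, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Per-class and mean Dice of a predicted label stack
#'
#' Pools intersection and mask sizes over all sections (one global Dice
#' per class), then averages over foreground classes.
#'
#' @param pred,gt aligned [label_stack()]s.
#' @param catalog a [class_catalog()] (defaults to the ground truth's).
#' @param foreground_only exclude the background from the mean?
#' @return tibble `(class, name, dice)` with the mean in `attr(,"mean_dice")`.
#' @export
evaluate_stack_dice <- function(pred, gt, catalog = gt$catalog,
                                foreground_only = TRUE) {
  if (pred$n_sections != gt$n_sections)
    stop("stacks have different lengths")
  ids <- catalog$class_ids
  inter <- sz <- stats::setNames(numeric(length(ids)), ids)
  for (n in seq_len(gt$n_sections)) {
    if (!identical(dim(pred$sections[[n]]), dim(gt$sections[[n]])))
      stop(sprintf("section %d shape mismatch", n))
    for (j in seq_along(ids)) {
      p <- pred$sections[[n]] == ids[j]
      r <- gt$sections[[n]] == ids[j]
      inter[j] <- inter[j] + sum(p & r)
      sz[j] <- sz[j] + sum(p) + sum(r)
    }
  }
  dice <- ifelse(sz == 0, 1, 2 * inter / sz)
  out <- tibble::tibble(class = ids, name = catalog$names, dice = unname(dice))
  fg <- if (foreground_only) ids != catalog$background_id else rep(TRUE, length(ids))
  attr(out, "mean_dice") <- mean(dice[fg])
  out
}

# raw probability maps for every section (feature matrices cached)
predict_all_sections <- function(backbone, stack, feats) {
  lapply(seq_len(stack$n_sections), function(n)
    predict_probs(backbone, stack$sections[[n]], features = feats[[n]]))
}

# hard segmentation of the whole stack under the full constraints
segment_stack <- function(raw_probs, state) {
  label_stack(lapply(seq_len(state$n_sections), function(n)
    hard_segmentation(constrained_posterior(raw_probs[[n]], state, n))),
    state$catalog)
}

mean_eval_dice <- function(raw_probs, state, gt, config) {
  pred <- segment_stack(raw_probs, state)
  attr(evaluate_stack_dice(pred, gt, foreground_only = config$foreground_only),
       "mean_dice")
}

# per-class query-scope Dice, sharing one bounds-only hard segmentation
# per section (equals per_class_dice(scope = "query") class by class)
query_dice_row <- function(raw_probs, state) {
  ids <- state$catalog$class_ids
  hs <- vector("list", state$n_sections)
  for (n in seq_len(state$n_sections)) {
    if (any(state$A[n, ] == 1L))
      hs[[n]] <- hard_segmentation(
        constrained_posterior(raw_probs[[n]], state, n,
                              constraints = "bounds_only"))
  }
  stats::setNames(vapply(ids, function(c) {
    secs <- which(state$A[, as.character(c)] == 1L)
    if (length(secs) == 0L) return(0)
    mean(vapply(secs, function(n)
      dice_coefficient(hs[[n]] == c, annotated_mask(state, n, c)), numeric(1)))
  }, numeric(1)), as.character(ids))
}

# per-candidate entropy table for the H-family strategies
entropy_table <- function(strategy, backbone, stack, state, pool, feats,
                          config, t) {
  ids <- state$catalog$class_ids
  Hm <- matrix(0, state$n_sections, length(ids),
               dimnames = list(NULL, as.character(ids)))
  for (n in unique(pool$n)) {
    post <- if (strategy == "H_dropout") {
      mc_dropout_posterior(backbone, stack$sections[[n]], state, n,
                           S = config$mc_samples,
                           seed = config$seed + 60000L + 100L * t,
                           features = feats[[n]])
    } else {
      constrained_posterior(predict_probs(backbone, stack$sections[[n]],
                                          features = feats[[n]]), state, n)
    }
    for (c in pool$c[pool$n == n]) Hm[n, as.character(c)] <- class_entropy(post, c)
  }
  Hm
}

#' Run one active-learning experiment
#'
#' The full loop: bootstrap one annotation per class via the simulated
#' annotator, train initially on the partial labels and weak bounds, then
#' iterate (update boundary statistics -> predict -> record per-class Dice
#' -> score the pool under the chosen strategy -> query -> charge the
#' actual tracing cost -> fine-tune) until a stopping rule fires or the
#' pool is exhausted. Fully reproducible given `config$seed`; pass a
#' `snapshot` (from a previous result's `$snapshot`, or [load_snapshot()])
#' to resume an interrupted run bit-identically.
#'
#' @param stack an [image_stack()].
#' @param gt ground-truth [label_stack()] (drives the simulated annotator
#'   and the evaluation curve).
#' @param config an [experiment_config()].
#' @param bounds optional [weak_bounds()]; default extracted from `gt`.
#' @param snapshot optional mid-run snapshot to resume from.
#' @return A `segsuggest_run`: `log` (query log tibble), `curve`
#'   (cost-fraction vs mean Dice, bootstrap included as `t = 0`),
#'   `dice_history`, `final_labels`, `total_cost`, `bootstrap_cost`,
#'   `exhausted`, `snapshot`, `config`.
#' @export
run_active_learning <- function(stack, gt, config = experiment_config(max_iter = 10L),
                                bounds = NULL, snapshot = NULL) {
  if (is.null(bounds)) bounds <- extract_weak_bounds(gt)
  catalog <- gt$catalog
  total_cost <- total_annotation_cost(gt)
  oracle <- oracle_annotator(gt)
  loss <- if (config$strategy == "BDalpha_CE") "ce" else "mixed"
  tcfg <- config$train

  if (is.null(snapshot)) {
    state <- with_seed(config$seed, init_annotations(oracle, bounds))
    # bootstrap cost: charge each initial mask in annotation order
    boot_state <- annotation_state(lapply(gt$sections, dim), bounds, catalog)
    boot_cost <- 0L
    for (n in seq_len(state$n_sections)) {
      for (c in catalog$class_ids[state$A[n, ] == 1L]) {
        boot_cost <- boot_cost + actual_annotation_cost(gt, boot_state, n, c)
        boot_state <- apply_annotation(boot_state, n, c, answer_query(oracle, n, c))
      }
    }
    backbone <- new_mlp_backbone(length(catalog$class_ids),
                                 dropout_rate = config$dropout_rate,
                                 seed = config$seed)
    tcfg$seed <- config$seed + 1L
    backbone <- initial_train(backbone, stack, state, tcfg, loss = loss)
    feats <- lapply(stack$sections, function(s) backbone_features(backbone, s))
    raw <- predict_all_sections(backbone, stack, feats)
    history <- matrix(query_dice_row(raw, state), nrow = 1,
                      dimnames = list(NULL, as.character(catalog$class_ids)))
    cum <- as.integer(boot_cost)
    md <- mean_eval_dice(raw, state, gt, config)
    log <- tibble::tibble(t = integer(), section = integer(), class = integer(),
                          cost = integer(), cumulative_cost = integer(),
                          mean_dice = numeric())
    curve <- tibble::tibble(t = 0L, cum_cost = cum,
                            cum_cost_frac = cum / total_cost, mean_dice = md)
    t_next <- 1L
    current_section <- NULL
  } else {
    state <- snapshot$state; backbone <- snapshot$backbone
    history <- snapshot$history; cum <- snapshot$cum; log <- snapshot$log
    curve <- snapshot$curve; t_next <- snapshot$t_next
    current_section <- snapshot$current_section
    boot_cost <- snapshot$boot_cost
    feats <- lapply(stack$sections, function(s) backbone_features(backbone, s))
    raw <- predict_all_sections(backbone, stack, feats)
    md <- curve$mean_dice[nrow(curve)]
  }

  exhausted <- FALSE
  stop_now <- function(md, cum, t) {
    (!is.null(config$target_dice) && md >= config$target_dice) ||
      (!is.null(config$budget_frac) && cum / total_cost >= config$budget_frac) ||
      (!is.null(config$max_iter) && t > config$max_iter)
  }

  t <- t_next
  while (!stop_now(md, cum, t)) {
    pool <- candidate_pairs(state)
    if (nrow(pool) == 0L) { exhausted <- TRUE; break }
    if (config$strategy == "rand") {
      q <- with_seed(config$seed + 20000L + t, select_random(state))
    } else if (config$strategy == "uniform") {
      q <- with_seed(config$seed + 20000L + t,
                     select_uniform(state, current_section))
    } else {
      stats <- update_boundary_stats(state, epsilon = config$epsilon)
      if (config$strategy == "Dalpha") {
        off <- stats$B; diag(off) <- 0
        stats$B <- stats$B - off  # keep the diagonal only
      }
      R <- effort_table(stats, state)
      dtilde <- stats::setNames(vapply(catalog$class_ids, function(c)
        predict_dice(history, c, alpha = config$alpha), numeric(1)),
        as.character(catalog$class_ids))
      needs_H <- config$strategy %in% c("HBDalpha", "HDalpha", "HB", "H", "H_dropout")
      Hm <- if (needs_H)
        entropy_table(config$strategy, backbone, stack, state, pool, feats,
                      config, t) else NULL
      scores <- score_candidates(config$strategy, pool, dtilde = dtilde,
                                 R = R, entropy = Hm)
      q <- select_query(scores)
    }
    cost <- actual_annotation_cost(gt, state, q$n, q$c)
    state <- apply_annotation(state, q$n, q$c, answer_query(oracle, q$n, q$c))
    cum <- cum + cost
    current_section <- q$n
    tcfg$seed <- config$seed + 40000L + t
    backbone <- finetune(backbone, stack, state, tcfg, loss = loss)
    raw <- predict_all_sections(backbone, stack, feats)
    history <- rbind(history, query_dice_row(raw, state))
    md <- mean_eval_dice(raw, state, gt, config)
    log <- dplyr::bind_rows(log, tibble::tibble(
      t = t, section = q$n, class = q$c, cost = as.integer(cost),
      cumulative_cost = as.integer(cum), mean_dice = md))
    curve <- dplyr::bind_rows(curve, tibble::tibble(
      t = t, cum_cost = as.integer(cum), cum_cost_frac = cum / total_cost,
      mean_dice = md))
    t <- t + 1L
  }

  snapshot <- list(state = state, backbone = backbone, history = history,
                   cum = cum, log = log, curve = curve, t_next = t,
                   current_section = current_section, boot_cost = boot_cost)
  structure(list(log = log, curve = curve,
                 dice_history = tibble::as_tibble(history),
                 final_labels = segment_stack(raw, state),
                 total_cost = total_cost, bootstrap_cost = boot_cost,
                 exhausted = exhausted, snapshot = snapshot, config = config),
            class = "segsuggest_run")
}

#' @export
print.segsuggest_run <- function(x, ...) {
  cat(sprintf("<segsuggest_run> strategy %s, %d quer%s, effort %.1f%%, mean Dice %.3f%s\n",
              x$config$strategy, nrow(x$log), if (nrow(x$log) == 1) "y" else "ies",
              100 * x$curve$cum_cost_frac[nrow(x$curve)],
              x$curve$mean_dice[nrow(x$curve)],
              if (x$exhausted) " (pool exhausted)" else ""))
  invisible(x)
}

#' Save / load a mid-run snapshot
#' @param run a `segsuggest_run` (its `$snapshot` is saved).
#' @param path file path.
#' @return `path` / the snapshot list.
#' @export
save_snapshot <- function(run, path) {
  saveRDS(run$snapshot, path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) readRDS(path)

#' Effort fraction at which a run first reaches a Dice target
#'
#' @param curve a run's `curve` tibble.
#' @param target mean Dice target.
#' @return the cumulative cost fraction at the first crossing, or `Inf`
#'   if the run never reached the target (censored at its last point).
#' @export
effort_to_dice <- function(curve, target) {
  hit <- which(curve$mean_dice >= target)
  if (length(hit) == 0L) return(Inf)
  curve$cum_cost_frac[hit[1]]
}

#' Mean Dice achieved within an effort budget
#'
#' @param curve a run's `curve` tibble.
#' @param budget cost fraction in \[0, 1\].
#' @return the last mean Dice recorded at cost fraction <= `budget`
#'   (`NA` if the bootstrap alone exceeds the budget).
#' @export
dice_at_budget <- function(curve, budget) {
  ok <- which(curve$cum_cost_frac <= budget)
  if (length(ok) == 0L) return(NA_real_)
  curve$mean_dice[max(ok)]
}

#' Compare query strategies on one stack
#'
#' Runs every strategy with every seed (stochastic strategies are thereby
#' averaged over the seed list) and summarises effort-to-target-Dice and
#' Dice-at-budget per strategy.
#'
#' @param stack,gt,bounds as in [run_active_learning()].
#' @param strategies character vector of strategy names (>= 2).
#' @param seeds integer vector, default `1:5`.
#' @param config base [experiment_config()] (its strategy/seed are
#'   overridden per run).
#' @param targets Dice targets for the effort summaries, default 0.80.
#' @param budgets cost-fraction budgets for the Dice summaries.
#' @return A `segsuggest_comparison`: `curves` (strategy, seed, t,
#'   cum_cost_frac, mean_dice), `summary` (per strategy medians), `logs`.
#' @export
compare_strategies <- function(stack, gt, strategies, seeds = 1:5,
                               config = experiment_config(budget_frac = 1),
                               bounds = NULL, targets = 0.80,
                               budgets = c(0.3, 0.45, 0.6)) {
  if (length(strategies) < 2L) stop("compare at least two strategies")
  grid <- tidyr::expand_grid(strategy = strategies, seed = as.integer(seeds))
  runs <- purrr::pmap(grid, function(strategy, seed) {
    cfg <- config
    cfg$strategy <- strategy
    cfg$seed <- seed
    run_active_learning(stack, gt, cfg, bounds = bounds)
  })
  curves <- purrr::pmap_dfr(
    list(grid$strategy, grid$seed, runs),
    function(strategy, seed, run)
      dplyr::mutate(run$curve, strategy = strategy, seed = seed,
                    .before = 1))
  per_run <- purrr::pmap_dfr(
    list(grid$strategy, grid$seed, runs),
    function(strategy, seed, run) {
      eff <- stats::setNames(
        vapply(targets, function(tg) effort_to_dice(run$curve, tg), numeric(1)),
        paste0("effort_to_dice_", format(targets)))
      dab <- stats::setNames(
        vapply(budgets, function(b) dice_at_budget(run$curve, b), numeric(1)),
        paste0("dice_at_", format(budgets)))
      tibble::tibble(strategy = strategy, seed = seed, !!!eff, !!!dab,
                     final_dice = run$curve$mean_dice[nrow(run$curve)])
    })
  summary <- per_run |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(dplyr::across(-"seed", stats::median), .groups = "drop")
  logs <- purrr::pmap_dfr(
    list(grid$strategy, grid$seed, runs),
    function(strategy, seed, run)
      dplyr::mutate(run$log, strategy = strategy, seed = seed, .before = 1))
  structure(list(curves = curves, per_run = per_run, summary = summary,
                 logs = logs, targets = targets, budgets = budgets),
            class = "segsuggest_comparison")
}

#' @export
print.segsuggest_comparison <- function(x, ...) {
  cat("<segsuggest_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' Write a run or comparison report to a directory
#'
#' For a run: the query log (`query_log.csv`, fixed header), the
#' Dice-vs-effort curve (`curve.csv`), a summary JSON, and the per-
#' iteration annotation snapshot (`annotations.csv`: which structure on
#' which section, in order). For a comparison: the pooled curves and logs
#' (`strategy,seed,t,section,class,cost,cum_cost_frac,mean_dice`) and the
#' summary table. Idempotent: re-running overwrites identical files.
#'
#' @param x a `segsuggest_run` or `segsuggest_comparison`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "segsuggest_run")) {
    save_log(x$log, file.path(path, "query_log.csv"))
    readr::write_csv(x$curve, file.path(path, "curve.csv"))
    readr::write_csv(dplyr::transmute(x$log, t = .data$t, section = .data$section,
                                      class = .data$class),
                     file.path(path, "annotations.csv"))
    summary <- c(unclass(glance(x)),
                 list(config = lapply(unclass(x$config), function(v)
                   if (is.list(v)) unclass(v) else v)))
    jsonlite::write_json(summary, file.path(path, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  } else if (inherits(x, "segsuggest_comparison")) {
    combined <- dplyr::left_join(
      x$logs,
      dplyr::select(x$curves, "strategy", "seed", "t", "cum_cost_frac"),
      by = c("strategy", "seed", "t"))
    readr::write_csv(dplyr::select(combined, "strategy", "seed", "t", "section",
                                   "class", "cost", "cum_cost_frac", "mean_dice"),
                     file.path(path, "queries.csv"))
    readr::write_csv(x$curves, file.path(path, "curves.csv"))
    readr::write_csv(x$summary, file.path(path, "summary.csv"))
    jsonlite::write_json(x$summary, file.path(path, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else stop("no report writer for this object")
  invisible(path)
}
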
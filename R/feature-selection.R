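#' Feature budget from the observations-per-parameter rule of thumb
#'
#' One feature per 20 observations, `floor(n / 20)`; with the planned 240
#' observations of the default study this is 12.
#'
#' @param n_observations Number of labeled observations.
#' @return Integer budget (>= 1; a warning and budget 1 below 20
#'   observations).
#' @export
max_feature_budget <- function(n_observations) {
  if (n_observations < 20) {
    warning("fewer than 20 observations; feature budget forced to 1",
            call. = FALSE)
    return(1L)
  }
  as.integer(floor(n_observations / 20))
}

new_feature_subset <- function(method, features, objective_value = NA_real_,
                               trajectory = NULL, seed = NULL) {
  structure(list(method = method, features = features,
                 objective_value = objective_value,
                 trajectory = trajectory, seed = seed),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("Feature subset (", x$method, "): ", length(x$features),
      " feature(s)\n  ", paste(x$features, collapse = ", "), "\n", sep = "")
  if (!is.na(x$objective_value))
    cat(sprintf("  objective value %.4f\n", x$objective_value))
  invisible(x)
}

#' Significance-filter feature selection
#'
#' Keeps features with Welch p below `alpha`, ranked by |t| descending
#' (ties by name), truncated to the budget. If nothing is significant the
#' single largest-|t| feature is returned with a warning.
#'
#' @param stats An [index_stats()] table.
#' @param max_features Feature budget.
#' @param alpha Significance level.
#' @return A `feature_subset`.
#' @export
select_filter_t <- function(stats, max_features = 12, alpha = 0.05) {
  ord <- stats[order(-abs(stats$t), stats$index), , drop = FALSE]
  sig <- ord$index[ord$p < alpha]
  if (!length(sig)) {
    warning("no feature significant at alpha = ", alpha,
            "; falling back to the top |t| feature", call. = FALSE)
    sig <- ord$index[1]
  }
  new_feature_subset("t_filter", head(sig, max_features))
}

#' Fisher-score filter feature selection
#'
#' Top `max_features` features by Fisher score, ties broken by feature name
#' (lexicographic) for determinism.
#'
#' @inheritParams select_filter_t
#' @return A `feature_subset`.
#' @export
select_filter_fisher <- function(stats, max_features = 12) {
  ord <- stats[order(-stats$fisher, stats$index), , drop = FALSE]
  new_feature_subset("fisher_filter", head(ord$index, max_features))
}

#' Sequential forward selection (SFS) wrapper
#'
#' Greedy subset growth maximizing the objective (the classifier's balanced
#' accuracy for wrapper selection): starting from the empty set, each step
#' adds the feature with the largest objective gain and stops when the
#' budget is reached or no candidate strictly improves the objective.
#' Ties go to the earliest feature in `features` order.
#'
#' @param objective Function mapping a character vector of feature names to
#'   a scalar to maximize.
#' @param features Candidate feature names.
#' @param max_features Feature budget.
#' @return A `feature_subset` with the accepted-step `trajectory` of
#'   objective values (non-decreasing by construction).
#' @export
select_sfs <- function(objective, features = feature_names(),
                       max_features = 12) {
  current <- character(0)
  best_val <- -Inf
  trajectory <- numeric(0)
  while (length(current) < max_features) {
    candidates <- setdiff(features, current)
    if (!length(candidates)) break
    vals <- vapply(candidates, function(f) objective(c(current, f)),
                   numeric(1))
    i <- which.max(vals)  # first maximum = earliest feature order
    if (vals[[i]] <= best_val && length(current) > 0) break
    current <- c(current, candidates[i])
    best_val <- vals[[i]]
    trajectory <- c(trajectory, best_val)
  }
  new_feature_subset("sfs", current, best_val, trajectory)
}

#' Genetic-algorithm wrapper feature selection
#'
#' Subsets are bit-string chromosomes over the candidate features. Fitness
#' is the objective after a hard budget repair (randomly clearing set bits
#' until the subset fits the budget; empty chromosomes get one random bit).
#' Generations use tournament selection, uniform crossover, per-bit
#' mutation and elitism; the best-ever subset is returned. Fixed seed gives
#' a reproducible result.
#'
#' @inheritParams select_sfs
#' @param population Population size (>= 2).
#' @param generations Number of generations.
#' @param crossover_p Probability of uniform crossover per mating.
#' @param mutation_p Per-bit mutation probability.
#' @param elitism Number of elites copied unchanged.
#' @param tournament Tournament size for selection.
#' @param seed Integer seed.
#' @return A `feature_subset` with the per-generation best-ever
#'   `trajectory` (non-decreasing thanks to elitism).
#' @export
select_ga <- function(objective, features = feature_names(),
                      max_features = 12, population = 40, generations = 50,
                      crossover_p = 0.8, mutation_p = 0.02, elitism = 2,
                      tournament = 3, seed = 1) {
  if (population < 2) stop("population must be >= 2", call. = FALSE)
  nf <- length(features)
  cache <- new.env(parent = emptyenv())
  fitness <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- objective(features[bits])
    cache[[key]] <- v
    v
  }
  repair <- function(bits) {
    on <- which(bits)
    if (length(on) > max_features) {
      drop <- sample(on, length(on) - max_features)
      bits[drop] <- FALSE
    } else if (!length(on)) {
      bits[sample.int(nf, 1)] <- TRUE
    }
    bits
  }
  with_seed(seed, {
    pop <- lapply(seq_len(population), function(i) {
      repair(runif(nf) < max_features / nf)
    })
    fit <- vapply(pop, fitness, numeric(1))
    best_bits <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    trajectory <- numeric(generations)
    for (g in seq_len(generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- pop[ord[seq_len(min(elitism, population))]]
      while (length(newpop) < population) {
        pick <- function() {
          idx <- sample.int(population, min(tournament, population))
          pop[[idx[which.max(fit[idx])]]]
        }
        p1 <- pick(); p2 <- pick()
        if (runif(1) < crossover_p) {
          mask <- runif(nf) < 0.5
          c1 <- ifelse(mask, p1, p2)
          c2 <- ifelse(mask, p2, p1)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (length(newpop) >= population) break
          flip <- runif(nf) < mutation_p
          child <- xor(child, flip)
          newpop[[length(newpop) + 1L]] <- repair(child)
        }
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1))
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_bits <- pop[[which.max(fit)]]
      }
      trajectory[g] <- best_fit
    }
    new_feature_subset("ga", features[best_bits], best_fit, trajectory,
                       seed = seed)
  })
}

#' Run one of the five feature-selection regimes
#'
#' Dispatches to all-inclusion, the significance filter, the Fisher filter,
#' SFS or the GA. Filters need `stats`; wrappers need an `objective`.
#'
#' @param method One of `"all"`, `"t_filter"`, `"fisher_filter"`, `"sfs"`,
#'   `"ga"`.
#' @param stats An [index_stats()] table (filter methods).
#' @param objective Objective function over feature-name vectors (wrapper
#'   methods); see [wrapper_objective()].
#' @param features Candidate features.
#' @param max_features Budget (ignored by `"all"`).
#' @param alpha Significance level for the t filter.
#' @param ga Named list of GA settings overriding [select_ga()] defaults.
#' @param seed Seed for the GA.
#' @return A `feature_subset`.
#' @export
select_features <- function(method = c("all", "t_filter", "fisher_filter",
                                       "sfs", "ga"),
                            stats = NULL, objective = NULL,
                            features = feature_names(), max_features = 12,
                            alpha = 0.05, ga = list(), seed = 1) {
  method <- match.arg(method)
  if (method %in% c("t_filter", "fisher_filter") && is.null(stats))
    stop("filter methods require stats", call. = FALSE)
  if (method %in% c("sfs", "ga") && is.null(objective))
    stop("wrapper methods require an objective", call. = FALSE)
  switch(method,
    all = new_feature_subset("all", features),
    t_filter = select_filter_t(stats, max_features, alpha),
    fisher_filter = select_filter_fisher(stats, max_features),
    sfs = select_sfs(objective, features, max_features),
    ga = do.call(select_ga, c(list(objective = objective,
                                   features = features,
                                   max_features = max_features,
                                   seed = seed), ga))
  )
}
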
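# Genetic function approximation: a genetic algorithm over descriptor
# subsets, each scored by fitting an OLS model and evaluating the Friedman
# lack-of-fit. Linear terms only; the population-based search is the point
# (it returns a ranked family of equations, not a single model).

#' GFA search configuration
#'
#' @param population_size number of descriptor subsets per generation.
#' @param generations maximum number of generations.
#' @param min_terms,max_terms bounds on model size (number of descriptors).
#' @param d Friedman smoothing parameter (default 0.5).
#' @param mutation_rate,crossover_rate per-child operator probabilities.
#' @param elitism number of best subsets copied unchanged each generation.
#' @param seed integer seed (required; the search has no other entropy
#'   source).
#' @param stagnation_patience stop after this many generations without
#'   improvement of the best LOF.
#' @param numerator LOF numerator variant, see [lof()].
#' @param allow_overfit override the Topliss-style guard that refuses
#'   `max_terms > M/5` (a warning is emitted instead of an error).
#' @return An object of class `gfa_config`.
#' @export
gfa_config <- function(population_size = 100, generations = 500,
                       min_terms = 2, max_terms = 8, d = 0.5,
                       mutation_rate = 0.1, crossover_rate = 0.9,
                       elitism = 2, seed, stagnation_patience = 50,
                       numerator = c("sse_over_m", "see"),
                       allow_overfit = FALSE) {
  if (missing(seed)) stop_named("gfa_config: seed is required")
  numerator <- match.arg(numerator)
  stopifnot(population_size >= 1, generations >= 1, min_terms >= 1,
            max_terms >= min_terms, d >= 0,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            elitism >= 0, stagnation_patience >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 min_terms = as.integer(min_terms),
                 max_terms = as.integer(max_terms), d = d,
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 stagnation_patience = as.integer(stagnation_patience),
                 numerator = numerator, allow_overfit = allow_overfit),
            class = "gfa_config")
}

#' Genetic function approximation over descriptor subsets
#'
#' Evolves a population of descriptor subsets: fitness is the Friedman
#' lack-of-fit of the OLS fit on the training data (lower is better),
#' parents are drawn by rank-based selection, children are produced by
#' one-point crossover on the sorted descriptor sets (duplicates repaired,
#' size clamped to `[min_terms, max_terms]`), and mutation swaps one
#' descriptor for an outside one or grows/shrinks the set. Elites survive
#' unchanged, duplicate subsets are collapsed, and the search stops at
#' `generations` or after `stagnation_patience` generations without
#' improvement. Fully reproducible from `config$seed`.
#'
#' @param dataset training [qsar_dataset()] (pretreated).
#' @param config a [gfa_config()].
#' @return An object of class `gfa_result`: a list with `models` (list of
#'   `list(model = mlr_model, lof = lof_score)` sorted by increasing LOF),
#'   `best_lof_history` (best LOF per generation), `generations_run`, and
#'   `config`.
#' @export
gfa_search <- function(dataset, config) {
  stopifnot(inherits(dataset, "qsar_dataset"), inherits(config, "gfa_config"))
  X <- dataset$X; y <- dataset$y
  M <- nrow(X); K <- ncol(X)
  if (K < config$min_terms)
    stop_named("descriptor pool (%d) smaller than min_terms (%d)", K,
               config$min_terms)
  if (config$max_terms >= M - 1L)
    stop_named("max_terms must be < n_train - 1")
  if (config$max_terms > M / 5) {
    if (!config$allow_overfit)
      stop_named("max_terms = %d exceeds the Topliss-style guard M/5 = %.1f; set allow_overfit = TRUE to override",
                 config$max_terms, M / 5)
    warning(sprintf("max_terms = %d exceeds M/5 = %.1f: risk of chance correlation",
                    config$max_terms, M / 5), call. = FALSE)
  }

  cache <- new.env(parent = emptyenv())
  score <- function(idx) {
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- .lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    sse <- sum(fit$residuals^2)
    val <- lof(sse, M = M, p = length(idx), d = config$d,
               numerator = config$numerator)$lof
    cache[[key]] <- val
    val
  }
  clamp <- function(idx) {
    idx <- sort(unique(idx))
    while (length(idx) > config$max_terms)
      idx <- idx[-sample.int(length(idx), 1L)]
    while (length(idx) < config$min_terms) {
      pool <- setdiff(seq_len(K), idx)
      idx <- sort(c(idx, pool[sample.int(length(pool), 1L)]))
    }
    idx
  }
  mutate <- function(idx) {
    op <- sample(c("swap", "grow", "shrink"), 1L)
    pool <- setdiff(seq_len(K), idx)
    if (op == "grow" && length(idx) < config$max_terms && length(pool))
      sort(c(idx, pool[sample.int(length(pool), 1L)]))
    else if (op == "shrink" && length(idx) > config$min_terms)
      sort(idx[-sample.int(length(idx), 1L)])
    else if (length(pool))
      sort(c(idx[-sample.int(length(idx), 1L)],
             pool[sample.int(length(pool), 1L)]))
    else idx
  }
  crossover <- function(a, b) {
    cut_a <- sample.int(length(a), 1L)
    cut_b <- sample.int(length(b), 1L)
    clamp(c(a[seq_len(cut_a)], b[seq(cut_b, length(b))]))
  }

  with_seed(config$seed, {
    pop <- list()
    seen <- new.env(parent = emptyenv())
    add_unique <- function(pop, idx, tries = 20L) {
      for (t in seq_len(tries)) {
        key <- paste(idx, collapse = ",")
        if (is.null(seen[[key]])) { seen[[key]] <- TRUE
          pop[[length(pop) + 1L]] <- idx; return(pop) }
        idx <- mutate(idx)
      }
      pop
    }
    attempts <- 0L
    while (length(pop) < config$population_size &&
           attempts < 50L * config$population_size) {
      s <- sample(seq.int(config$min_terms, config$max_terms), 1L)
      pop <- add_unique(pop, sort(sample.int(K, min(s, K))))
      attempts <- attempts + 1L
    }

    best_hist <- numeric(0)
    best <- Inf; stagnant <- 0L; gen <- 0L
    repeat {
      gen <- gen + 1L
      fitness <- vapply(pop, score, 0)
      ord <- order(fitness)
      pop <- pop[ord]; fitness <- fitness[ord]
      if (fitness[1L] < best - 1e-12) { best <- fitness[1L]; stagnant <- 0L }
      else stagnant <- stagnant + 1L
      best_hist <- c(best_hist, fitness[1L])  # per-generation best
      if (gen >= config$generations || stagnant >= config$stagnation_patience)
        break

      N <- length(pop)
      w <- rev(seq_len(N))  # rank weights: best gets N
      nextgen <- list()
      seen <- new.env(parent = emptyenv())
      for (e in seq_len(min(config$elitism, N)))
        nextgen <- add_unique(nextgen, pop[[e]], tries = 1L)
      guard <- 0L
      while (length(nextgen) < config$population_size &&
             guard < 50L * config$population_size) {
        guard <- guard + 1L
        pa <- pop[[sample.int(N, 1L, prob = w)]]
        child <- if (stats::runif(1) < config$crossover_rate) {
          pb <- pop[[sample.int(N, 1L, prob = w)]]
          crossover(pa, pb)
        } else pa
        if (stats::runif(1) < config$mutation_rate) child <- mutate(child)
        nextgen <- add_unique(nextgen, child)
      }
      # pathological configs (tiny pool) may not fill uniquely; pad with elites
      i <- 1L
      while (length(nextgen) < config$population_size) {
        nextgen[[length(nextgen) + 1L]] <- pop[[i]]
        i <- i %% length(pop) + 1L
      }
      pop <- nextgen
    }

    fitness <- vapply(pop, score, 0)
    keys <- vapply(pop, paste, "", collapse = ",")
    keep <- !duplicated(keys)
    pop <- pop[keep]; fitness <- fitness[keep]
    ord <- order(fitness)
    models <- lapply(ord, function(i) {
      idx <- pop[[i]]
      m <- fit_mlr(X[, idx, drop = FALSE], y)
      list(model = m,
           lof = lof(m$sse, M = M, p = length(idx), d = config$d,
                     numerator = config$numerator))
    })
    structure(list(models = models, best_lof_history = best_hist,
                   generations_run = gen, config = config),
              class = "gfa_result")
  })
}

#' @export
print.gfa_result <- function(x, top = 5L, ...) {
  cat(sprintf("<gfa_result> %d unique models after %d generations\n",
              length(x$models), x$generations_run))
  for (i in seq_len(min(top, length(x$models)))) {
    m <- x$models[[i]]
    cat(sprintf("  %d. LOF = %.5g, R2 = %.4f: %s\n", i, m$lof$lof,
                m$model$r2, paste(names(m$model$coefficients),
                                  collapse = " + ")))
  }
  invisible(x)
}
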
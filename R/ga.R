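# Genetic-algorithm hyperparameter tuning. Chromosomes are vectors on
# the unit interval, one gene per hyperparameter, decoded through the
# spec's search space (linear for "num", rounded for "int", log-linear
# for "log").

decode_genome <- function(genome, space) {
  out <- list()
  for (k in seq_along(space)) {
    s <- space[[k]]; g <- genome[k]
    v <- switch(s$type,
                num = s$min + g * (s$max - s$min),
                int = as.integer(round(s$min + g * (s$max - s$min))),
                log = exp(log(s$min) + g * (log(s$max) - log(s$min))),
                stop_input("unknown space type: ", s$type))
    out[[names(space)[k]]] <- v
  }
  out
}

#' Genetic-algorithm hyperparameter search
#'
#' Maximizes the mean k-fold cross-validated \eqn{R^2} of a learner
#' over its hyperparameter search space with a simple generational GA:
#' tournament selection, one-point crossover, per-gene uniform
#' mutation, elitism of one. Deterministic under `seed` (the fitness of
#' a genome is evaluated with a fixed fold assignment and fit seed).
#'
#' @param spec a [learner_spec()] with a nonempty `space`.
#' @param train data.frame containing the target column.
#' @param target target column name.
#' @param k cross-validation folds for the fitness.
#' @param seed RNG seed.
#' @param pop_size population size (default 30).
#' @param generations number of generations (default 20); 0 evaluates
#'   only the random initial population.
#' @param p_crossover one-point crossover probability.
#' @param p_mutation per-gene mutation probability.
#' @param tournament tournament size.
#' @return the spec with `params` replaced by the best hyperparameters
#'   found; attribute `"ga_history"` carries best fitness per
#'   generation.
#' @export
ga_tune <- function(spec, train, target = "moisture", k = 5L, seed = 1L,
                    pop_size = 30L, generations = 20L,
                    p_crossover = 0.9, p_mutation = 0.1,
                    tournament = 3L) {
  stopifnot(inherits(spec, "learner_spec"))
  if (length(spec$space) == 0L)
    stop_input("learner '", spec$name, "' has an empty search space")
  ng <- length(spec$space)
  folds <- make_folds(nrow(train), k, seed = child_seed(seed, 777))
  X <- train[setdiff(names(train), target)]
  y <- train[[target]]
  fitness <- function(genome) {
    params <- decode_genome(genome, spec$space)
    r2 <- vapply(seq_len(k), function(fold) {
      tr <- folds != fold
      fit <- spec$fit(X[tr, , drop = FALSE], y[tr], params,
                      child_seed(seed, fold))
      pred <- spec$predict(fit, X[!tr, , drop = FALSE])
      m <- tryCatch(regression_metrics(y[!tr], pred)$r2,
                    error = function(e) -Inf)
      m
    }, numeric(1))
    mean(r2)
  }
  hist <- numeric(0)
  best <- with_seed(seed, {
    pop <- matrix(runif(pop_size * ng), pop_size, ng)
    fit_vals <- apply(pop, 1, fitness)
    for (gen in seq_len(generations)) {
      elite <- which.max(fit_vals)
      newpop <- matrix(0, pop_size, ng)
      newpop[1, ] <- pop[elite, ]
      for (i in seq(2L, pop_size)) {
        pick <- function() {
          cand <- sample(pop_size, tournament)
          cand[which.max(fit_vals[cand])]
        }
        a <- pop[pick(), ]; b <- pop[pick(), ]
        child <- if (runif(1) < p_crossover && ng > 1L) {
          cut <- sample(ng - 1L, 1L)
          c(a[seq_len(cut)], b[seq(cut + 1L, ng)])
        } else a
        mut <- runif(ng) < p_mutation
        child[mut] <- runif(sum(mut))
        newpop[i, ] <- child
      }
      pop <- newpop
      fit_vals <- apply(pop, 1, fitness)
      hist <- c(hist, max(fit_vals))
    }
    pop[which.max(fit_vals), ]
  })
  spec$params <- decode_genome(best, spec$space)
  attr(spec, "ga_history") <- hist
  spec
}
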
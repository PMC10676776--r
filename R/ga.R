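# Genetic algorithm for artificial ORI design. The population starts from
# 1000-bp homopolymers (all A or all G), evolves under four mutation modes
# (point, insertion, deletion, segment reversal) with truncation selection
# and elitism, and terminates once the minimum population fitness exceeds
# the threshold (default 0.5) or the generation budget is exhausted. The
# fitness function is pluggable; by default the trained classifier's ORI
# probability (see [classifier_fitness()]).

#' Genetic-algorithm configuration
#'
#' Mutation rates are per-offspring probabilities that the mode fires;
#' `point_events` single-base substitutions are applied when the point mode
#' fires (the per-offspring mutation dose, chosen so a 1000-bp homopolymer
#' can traverse composition space within the generation budget). All
#' defaults are exposed; none are claimed to reproduce unpublished settings.
#'
#' @param pop_size Population size (default 100).
#' @param init_length Initial sequence length in bp (default 1000).
#' @param init_base `"A"` or `"G"` homopolymer initialization.
#' @param point_rate,ins_rate,del_rate,sv_rate Per-offspring probabilities
#'   of point mutation (default 1), insertion (0.1), deletion (0.1) and
#'   structural variation (0.05).
#' @param point_events Number of point mutations applied when the point mode
#'   fires (default 10).
#' @param sv_segment_range Length interval of the reversed segment.
#' @param length_bounds Hard sequence-length interval; insertions/deletions
#'   that would cross a bound are skipped, not failed.
#' @param survivor_fraction Fraction kept by truncation selection.
#' @param fitness_threshold Termination threshold on the population minimum
#'   fitness (default 0.5).
#' @param max_generations Generation budget (default 500).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100L, init_length = 1000L, init_base = "A",
                      point_rate = 1.0, ins_rate = 0.1, del_rate = 0.1,
                      sv_rate = 0.05, point_events = 10L,
                      sv_segment_range = c(50L, 200L),
                      length_bounds = c(500L, 2000L),
                      survivor_fraction = 0.5, fitness_threshold = 0.5,
                      max_generations = 500L, seed = 1L) {
  init_base <- toupper(init_base)
  if (!(init_base %in% c("A", "G"))) {
    stop("`init_base` must be \"A\" or \"G\"", call. = FALSE)
  }
  rates <- c(point_rate, ins_rate, del_rate, sv_rate)
  stopifnot(pop_size >= 2L, init_length >= 1L,
            all(rates >= 0), all(rates <= 1), point_events >= 1L,
            survivor_fraction > 0, survivor_fraction < 1,
            max_generations >= 1L,
            length_bounds[1] <= init_length, init_length <= length_bounds[2],
            sv_segment_range[1] <= sv_segment_range[2])
  structure(list(pop_size = as.integer(pop_size),
                 init_length = as.integer(init_length), init_base = init_base,
                 point_rate = point_rate, ins_rate = ins_rate,
                 del_rate = del_rate, sv_rate = sv_rate,
                 point_events = as.integer(point_events),
                 sv_segment_range = as.integer(sv_segment_range),
                 length_bounds = as.integer(length_bounds),
                 survivor_fraction = survivor_fraction,
                 fitness_threshold = fitness_threshold,
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Initial homopolymer population
#'
#' @param config A [ga_config()].
#' @return Tibble with columns `id`, `seq`, `fitness` (NA until evaluated).
#' @export
init_population <- function(config = ga_config()) {
  tibble::tibble(
    id = sprintf("ind_%03d", seq_len(config$pop_size)),
    seq = strrep(config$init_base, config$init_length),
    fitness = NA_real_
  )
}

# ---- mutation operators (draw from the current RNG stream) ------------------

#' Mutation operators
#'
#' `mutate_point()` replaces exactly one uniformly chosen position with a
#' uniformly chosen *different* base. `mutate_insertion()` adds one uniform
#' base at a uniform position; `mutate_deletion()` removes one uniform
#' position. `mutate_structural()` reverses a contiguous segment in place
#' (length uniform in `segment_range`, uniform start), preserving length and
#' base composition. All draw from R's current RNG stream; seed the stream
#' (or use [evolve()]) for reproducibility.
#'
#' @param seq DNA sequence string.
#' @return The mutated sequence string.
#' @export
mutate_point <- function(seq) {
  n <- nchar(seq)
  pos <- sample.int(n, 1L)
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(BASES, old), 1L)
  substr(seq, pos, pos) <- new
  seq
}

#' @rdname mutate_point
#' @export
mutate_insertion <- function(seq) {
  n <- nchar(seq)
  pos <- sample.int(n + 1L, 1L) - 1L  # insert after position pos (0 = front)
  base <- sample(BASES, 1L)
  paste0(substr(seq, 1L, pos), base, substr(seq, pos + 1L, n))
}

#' @rdname mutate_point
#' @export
mutate_deletion <- function(seq) {
  n <- nchar(seq)
  if (n <= 1L) return(seq)
  pos <- sample.int(n, 1L)
  paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + 1L, n))
}

#' @rdname mutate_point
#' @param segment_range Integer interval for the reversed segment length.
#' @export
mutate_structural <- function(seq, segment_range = c(50L, 200L)) {
  n <- nchar(seq)
  if (n < segment_range[1]) return(seq)  # too short: skipped, not failed
  len <- sample.int(min(segment_range[2], n) - segment_range[1] + 1L, 1L) +
    segment_range[1] - 1L
  start <- sample.int(n - len + 1L, 1L)
  mid <- paste(rev(strsplit(substr(seq, start, start + len - 1L), "",
                            fixed = TRUE)[[1]]), collapse = "")
  paste0(substr(seq, 1L, start - 1L), mid, substr(seq, start + len, n))
}

# apply each mode with its configured rate; length-bound violations skip the
# insertion/deletion rather than failing
mutate_offspring <- function(seq, config) {
  if (stats::runif(1) <= config$point_rate) {
    for (i in seq_len(config$point_events)) seq <- mutate_point(seq)
  }
  if (stats::runif(1) <= config$ins_rate &&
      nchar(seq) < config$length_bounds[2]) {
    seq <- mutate_insertion(seq)
  }
  if (stats::runif(1) <= config$del_rate &&
      nchar(seq) > config$length_bounds[1]) {
    seq <- mutate_deletion(seq)
  }
  if (stats::runif(1) <= config$sv_rate) {
    seq <- mutate_structural(seq, config$sv_segment_range)
  }
  seq
}

# evaluate any unset fitness values in one vectorized fitness call
evaluate_population <- function(pop, fitness_fn) {
  todo <- is.na(pop$fitness)
  if (any(todo)) {
    f <- fitness_fn(pop$seq[todo])
    if (length(f) != sum(todo) || !is.numeric(f)) {
      stop("fitness function must return one numeric value per sequence",
           call. = FALSE)
    }
    pop$fitness[todo] <- f
  }
  pop
}

#' One generation of selection and mutation
#'
#' Evaluates all unset fitness values, keeps the top `survivor_fraction` by
#' truncation selection (stable ties: earlier index wins; the best individual
#' always passes unmutated -- elitism), then refills to `pop_size` with
#' mutated copies of the survivors, each offspring applying every mutation
#' mode independently with its configured rate.
#'
#' @param pop Population tibble (`id`, `seq`, `fitness`).
#' @param fitness_fn Vectorized fitness function: character vector of
#'   sequences -> numeric vector.
#' @param config A [ga_config()].
#' @return The next evaluated population (same size).
#' @export
step_generation <- function(pop, fitness_fn, config = ga_config()) {
  stopifnot(nrow(pop) >= 1L)
  pop <- evaluate_population(pop, fitness_fn)
  n_keep <- max(1L, ceiling(config$pop_size * config$survivor_fraction))
  ord <- order(-pop$fitness)  # stable: ties broken by original index
  survivors <- pop[ord[seq_len(min(n_keep, nrow(pop)))], ]
  n_off <- config$pop_size - nrow(survivors)
  parents <- survivors$seq[rep_len(seq_len(nrow(survivors)), n_off)]
  offspring <- tibble::tibble(
    id = sprintf("ind_%03d", nrow(survivors) + seq_len(n_off)),
    seq = vapply(parents, mutate_offspring, character(1), config = config,
                 USE.NAMES = FALSE),
    fitness = NA_real_
  )
  survivors$id <- sprintf("ind_%03d", seq_len(nrow(survivors)))
  evaluate_population(dplyr::bind_rows(survivors, offspring), fitness_fn)
}

#' Evolve a sequence population under a fitness function
#'
#' Iterates [step_generation()] from the homopolymer initial population until
#' the population *minimum* fitness exceeds `fitness_threshold` or
#' `max_generations` is reached. Generation 0 is the evaluated initial
#' population (a population already above threshold terminates immediately).
#' The whole run is reproducible from `config$seed`.
#'
#' @param config A [ga_config()].
#' @param fitness_fn Vectorized fitness function (sequences -> numeric);
#'   e.g. [classifier_fitness()].
#' @return Object of class `ga_run`: `population` (final, with fitness),
#'   `trajectory` (per generation: min/mean/max fitness, mean GC content,
#'   mean length), `terminated_at` and the config.
#' @export
evolve <- function(config = ga_config(), fitness_fn) {
  stopifnot(inherits(config, "ga_config"), is.function(fitness_fn))
  withr::with_seed(config$seed, {
    pop <- evaluate_population(init_population(config), fitness_fn)
    traj <- vector("list", config$max_generations + 1L)
    traj[[1]] <- trajectory_row(0L, pop)
    gen <- 0L
    while (min(pop$fitness) <= config$fitness_threshold &&
           gen < config$max_generations) {
      gen <- gen + 1L
      pop <- step_generation(pop, fitness_fn, config)
      traj[[gen + 1L]] <- trajectory_row(gen, pop)
    }
  })
  structure(list(population = pop,
                 trajectory = dplyr::bind_rows(traj[!vapply(traj, is.null,
                                                            logical(1))]),
                 terminated_at = gen,
                 converged = min(pop$fitness) > config$fitness_threshold,
                 config = config),
            class = "ga_run")
}

trajectory_row <- function(gen, pop) {
  tibble::tibble(generation = gen,
                 min_fitness = min(pop$fitness),
                 mean_fitness = mean(pop$fitness),
                 max_fitness = max(pop$fitness),
                 mean_gc = mean(gc_content(pop$seq)),
                 mean_length = mean(nchar(pop$seq)))
}

#' @export
print.ga_run <- function(x, ...) {
  cat("<ga_run> ", x$terminated_at, " generation(s); ",
      if (x$converged) "converged" else "budget exhausted",
      "; min fitness ", signif(min(x$population$fitness), 4),
      "; mean GC ", signif(mean(gc_content(x$population$seq)), 4), "\n",
      sep = "")
  invisible(x)
}

#' Per-generation GA trajectory
#' @param x A `ga_run`.
#' @param ... Unused.
#' @return Tibble: generation, min/mean/max fitness, mean GC, mean length.
#' @export
tidy.ga_run <- function(x, ...) x$trajectory

#' One-row GA run summary
#' @param x A `ga_run`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.ga_run <- function(x, ...) {
  tibble::tibble(generations = x$terminated_at,
                 converged = x$converged,
                 min_fitness = min(x$population$fitness),
                 mean_fitness = mean(x$population$fitness),
                 mean_gc = mean(gc_content(x$population$seq)),
                 mean_length = mean(nchar(x$population$seq)))
}

#' Plot fitness and GC trajectories of a GA run
#' @param object A `ga_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_run <- function(object, ...) {
  tr <- object$trajectory
  long <- tidyr::pivot_longer(
    tr[c("generation", "min_fitness", "mean_fitness", "max_fitness",
         "mean_gc")],
    -"generation", names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Use a trained classifier as GA fitness
#'
#' Returns a pure, deterministic vectorized fitness function mapping DNA
#' sequences to the classifier's predicted ORI probability after Z-curve
#' encoding.
#'
#' @param model A trained `ori_model`.
#' @param zconfig The [zspace()] to encode candidates with; defaults to the
#'   Z-space the model was fitted with.
#' @return `function(seqs) -> numeric probabilities`.
#' @export
classifier_fitness <- function(model, zconfig = NULL) {
  stopifnot(inherits(model, "ori_model"))
  zconfig <- zconfig %||% model$zspace
  if (is.null(zconfig)) {
    stop("supply `zconfig`: the model does not carry one", call. = FALSE)
  }
  force(model)
  function(seqs) {
    enc <- encode_sequences(tibble::tibble(id = paste0("c", seq_along(seqs)),
                                           seq = seqs), zconfig)
    predict(model, z_matrix(enc))
  }
}
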
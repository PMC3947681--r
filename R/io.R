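# Model-spec files (YAML) and the command-line interface.

#' Read a model specification file
#'
#' The spec file is human-editable YAML with fields `n_pops`, `n_events`,
#' `incidence` (list of rows, populations x events), `rate_coeffs`
#' (events x populations), `initial_pops`, and optional `populations` /
#' `events` label lists.  Files failing [validate_model()] are rejected
#' unless `force = TRUE`.
#'
#' @param path file path.
#' @param force load even if structural validation fails.
#' @return A `linpop_model`.
#' @seealso [write_model_spec()]
#' @export
read_model_spec <- function(path, force = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  need <- c("n_pops", "n_events", "incidence", "rate_coeffs", "initial_pops")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("model spec is missing field(s): ",
                         paste(miss, collapse = ", "))
  N <- y$n_pops; E <- y$n_events
  # yaml collapses single-element rows/matrices to scalars
  to_mat <- function(x, nr, nc) {
    if (is.list(x)) do.call(rbind, lapply(x, unlist))
    else matrix(unlist(x), nr, nc, byrow = TRUE)
  }
  inc <- to_mat(y$incidence, N, E)
  rc <- to_mat(y$rate_coeffs, E, N)
  if (!all(dim(inc) == c(N, E))) {
    stop("`incidence` must be ", N, " rows of ", E, " values")
  }
  if (!all(dim(rc) == c(E, N))) {
    stop("`rate_coeffs` must be ", E, " rows of ", N, " values")
  }
  model <- linear_model(inc, rc, unlist(y$initial_pops),
                        pop_names = unlist(y$populations),
                        event_names = unlist(y$events),
                        validate = FALSE)
  rep <- validate_model(model)
  if (!rep$passed && !force) {
    stop("model spec fails validation:\n  ",
         paste(rep$violations$message, collapse = "\n  "))
  }
  model
}

#' Write a model specification file
#'
#' @param model a `linpop_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path) {
  y <- list(
    n_pops = model$n_pops,
    n_events = model$n_events,
    populations = as.list(model$pop_names),
    events = as.list(model$event_names),
    incidence = lapply(seq_len(model$n_pops),
                       function(i) as.integer(model$incidence[i, ])),
    rate_coeffs = lapply(seq_len(model$n_events),
                         function(a) as.numeric(model$rate_coeffs[a, ])),
    initial_pops = as.integer(model$initial_pops))
  yaml::write_yaml(y, path, precision = 17)  # lossless double round-trip
  invisible(path)
}

cli_usage <- function() {
  cat("usage: eventpgf <command> [options]\n",
      "commands:\n",
      "  validate <spec>                      check a model spec file\n",
      "  solve <spec> --t T [--truncation K] [--output F] [--pop-output F]\n",
      "                                       event-count distribution CSV\n",
      "  closed-form <family> --t-grid a,b,n [params] [--output F]\n",
      "       families: pure-death --M --rate | cascade --rates r1,r2,..\n",
      "                 cascade-mortality --rates .. --deaths ..\n",
      "                 drug-delivery --lambda l0,..,l3 --mu m0,..,m3\n",
      "  approx <spec> --scheme poisson|mn1|mn2 [--h-list h1,h2,..]\n",
      "       [--truncation K] [--output F]     one-step TV order test CSV\n",
      "  simulate <spec> --scheme ssa|mn1|mn2 --t-end T [--h H] [--runs R]\n",
      "       [--seed S] [--output F]           trajectory / ensemble CSV\n",
      "  compare <spec> --scheme mn1|mn2 --t-end T --h H --runs R\n",
      "       [--truncation K] [--seed S]       TV vs exact distribution\n",
      sep = "")
}

cli_opts <- function(args) {
  opts <- list(); pos <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        opts[[key]] <- TRUE; i <- i + 1
      } else { opts[[key]] <- args[i + 1]; i <- i + 2 }
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  list(opts = opts, pos = pos)
}

cli_num_list <- function(s) as.numeric(strsplit(s, ",")[[1]])

cli_emit <- function(df, output) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                        ~ signif(.x, 12)))
  if (is.null(output)) {
    write.csv(df, stdout(), row.names = FALSE)
  } else {
    write.csv(df, output, row.names = FALSE)
  }
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; the `exec/eventpgf`
#' script forwards `commandArgs(TRUE)` here.  Subcommands: `validate`,
#' `solve`, `closed-form`, `approx`, `simulate`, `compare`.  CSV goes to
#' stdout or `--output`; probabilities are printed with 12 significant
#' digits.  Exit codes: 0 success, 2 validation failure, 1 runtime
#' error, 64 usage error.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { cli_usage(); return(invisible(64L)) }
  cmd <- args[1]
  parsed <- cli_opts(args[-1])
  o <- parsed$opts; pos <- parsed$pos
  out <- o$output %||% NULL
  code <- tryCatch({
    switch(cmd,
      validate = {
        model <- read_model_spec(pos[1], force = TRUE)
        rep <- validate_model(model)
        print(rep)
        if (rep$passed) 0L else 2L
      },
      solve = {
        model <- read_model_spec(pos[1])
        t <- as.numeric(o$t)
        K <- if (!is.null(o$truncation)) as.numeric(o$truncation)
        d <- event_count_distribution(model, t, truncation = K)
        cli_emit(d, out)
        if (!is.null(o$`pop-output`)) {
          cli_emit(project_to_populations(d), o$`pop-output`)
        }
        0L
      },
      `closed-form` = {
        fam <- pos[1]
        tg <- cli_num_list(o$`t-grid`)
        tt <- seq(tg[1], tg[2], length.out = tg[3])
        df <- switch(fam,
          `pure-death` = {
            M <- as.numeric(o$M); rate <- as.numeric(o$rate)
            tibble::tibble(t = tt,
                           mean_deaths = M * (1 - exp(-rate * tt)),
                           p_all_alive = Re(pure_death_psi(M, rate, tt, 0)))
          },
          cascade = {
            spec <- cascade_spec(cli_num_list(o$rates))
            tibble::tibble(t = tt, exit_cdf = exit_time_cdf(spec)(tt))
          },
          `cascade-mortality` = {
            spec <- cascade_spec(cli_num_list(o$rates),
                                 cli_num_list(o$deaths))
            tibble::tibble(t = tt, exit_cdf = exit_time_cdf(spec)(tt))
          },
          `drug-delivery` = {
            stage_occupancy(cli_num_list(o$lambda), cli_num_list(o$mu), tt)
          },
          stop("unknown closed-form family: ", fam))
        cli_emit(df, out)
        0L
      },
      approx = {
        model <- read_model_spec(pos[1])
        hs <- if (!is.null(o$`h-list`)) cli_num_list(o$`h-list`) else 2^-(4:9)
        K <- if (!is.null(o$truncation)) as.numeric(o$truncation) else 8
        res <- order_of_accuracy(model, o$scheme, hs, truncation = K)
        message("estimated order: ", signif(res$slope, 4))
        cli_emit(res$table, out)
        0L
      },
      simulate = {
        model <- read_model_spec(pos[1])
        t_end <- as.numeric(o$`t-end`)
        seed <- if (!is.null(o$seed)) as.integer(o$seed)
        runs <- if (!is.null(o$runs)) as.integer(o$runs) else 1L
        if (runs > 1) {
          ens <- simulate_ensemble(model, t_end, runs, o$scheme,
                                   h = if (!is.null(o$h)) as.numeric(o$h),
                                   seed = seed)
          cli_emit(ens$distribution, out)
        } else if (o$scheme == "ssa") {
          cli_emit(ssa_simulate(model, t_end, seed = seed), out)
        } else {
          cli_emit(multinomial_step_simulate(
            model, t_end, as.numeric(o$h),
            order = as.integer(substr(o$scheme, 3, 3)), seed = seed), out)
        }
        0L
      },
      compare = {
        model <- read_model_spec(pos[1])
        t_end <- as.numeric(o$`t-end`)
        K <- if (!is.null(o$truncation)) as.numeric(o$truncation)
        exact <- event_count_distribution(model, t_end, truncation = K)
        ens <- simulate_ensemble(model, t_end, as.integer(o$runs), o$scheme,
                                 h = if (!is.null(o$h)) as.numeric(o$h),
                                 seed = if (!is.null(o$seed)) as.integer(o$seed))
        cmpr <- compare_to_exact(ens, exact)
        cli_emit(tibble::tibble(tv = cmpr$tv, n_flagged = cmpr$n_flagged), out)
        0L
      },
      { cli_usage(); 64L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
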
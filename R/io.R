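# all floating-point output uses 17 significant digits so that write/read
# round-trips reproduce doubles exactly
fmt17 <- function(x) sprintf("%.17g", x)

#' Write and read Pajek .net files
#'
#' Writes an [adjacency_structure] as `*Vertices` / `*Edges` (structural,
#' unweighted) or an [interaction_matrix] as `*Vertices` / `*Arcs`
#' (directed, weighted; self-couplings appear as loop arcs `i i w`).
#' Node indices are 1-based. Weights are printed at 17 significant digits,
#' so write - read - write reproduces identical bytes.
#'
#' @param network An [adjacency_structure] or [interaction_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(network, path) {
  if (inherits(network, "adjacency_structure")) {
    lines <- c(sprintf("*Vertices %d", network$n_nodes), "*Edges",
               sprintf("%d %d", network$edges[, 1L], network$edges[, 2L]))
  } else if (inherits(network, "interaction_matrix")) {
    W <- network$weights
    idx <- which(W != 0, arr.ind = TRUE)
    lines <- c(sprintf("*Vertices %d", network$n_nodes), "*Arcs",
               sprintf("%d %d %s", idx[, 1L], idx[, 2L], fmt17(W[idx])))
  } else stop_invalid("write_pajek: unsupported network object")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pajek
#' @return `read_pajek` returns an [adjacency_structure] (for `*Edges`
#'   files) or an [interaction_matrix] (for `*Arcs` files).
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("\\*Vertices\\s+", "", lines[1L], ignore.case = TRUE))
  marker <- lines[2L]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (grepl("^\\*Edges", marker, ignore.case = TRUE)) {
    if (length(body) == 0L)
      return(adjacency_structure(n, matrix(integer(0), ncol = 2)))
    parts <- do.call(rbind, strsplit(body, "\\s+"))
    adjacency_structure(n, cbind(as.integer(parts[, 1L]), as.integer(parts[, 2L])))
  } else if (grepl("^\\*Arcs", marker, ignore.case = TRUE)) {
    W <- matrix(0, n, n)
    if (length(body) > 0L) {
      parts <- do.call(rbind, strsplit(body, "\\s+"))
      W[cbind(as.integer(parts[, 1L]), as.integer(parts[, 2L]))] <-
        as.numeric(parts[, 3L])
    }
    interaction_matrix(W, topology = "pajek")
  } else stop_invalid("read_pajek: expected an *Edges or *Arcs section")
}

#' Dense CSV and MatrixMarket matrix I/O
#'
#' `write_matrix_csv`/`read_matrix_csv` store the full dense matrix (no
#' header, 17 significant digits). `write_matrix_mm`/`read_matrix_mm` use
#' the MatrixMarket coordinate format via the Matrix package.
#'
#' @param matrix An [interaction_matrix] or square numeric matrix.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return an
#'   [interaction_matrix].
#' @export
write_matrix_csv <- function(matrix, path) {
  W <- coerce_weights(matrix)
  lines <- apply(W, 1L, function(r) paste(fmt17(r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  W <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(W) <- NULL
  interaction_matrix(W, topology = "csv")
}

#' @rdname write_matrix_csv
#' @export
write_matrix_mm <- function(matrix, path) {
  W <- coerce_weights(matrix)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(W), "generalMatrix"),
                              "CsparseMatrix"), path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_mm <- function(path) {
  W <- as.matrix(Matrix::readMM(path))
  interaction_matrix(W, topology = "matrixmarket")
}

#' Weighted edge-list TSV export
#'
#' Writes the nonzero off-diagonal entries as a three-column TSV
#' (`src`, `dst`, `weight`) with 0-based node indices.
#'
#' @param matrix An [interaction_matrix] or square numeric matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(matrix, path) {
  W <- coerce_weights(matrix)
  idx <- which(W != 0 & row(W) != col(W), arr.ind = TRUE)
  lines <- c("src\tdst\tweight",
             sprintf("%d\t%d\t%s", idx[, 1L] - 1L, idx[, 2L] - 1L, fmt17(W[idx])))
  writeLines(lines, path)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

run_config_defaults <- function() {
  list(mode = "sweep", topology = "smallworld", n_nodes = 1000L,
       k_nn = 4L, p_rew = 0.05, m = 2L, m0 = 0L,
       seed_dim = 10L, seed_zeros = 82L, power = NULL, connectance = 0.1,
       scheme = "varied_position",
       sizes = c(100L, 200L, 300L, 400L, 500L),
       trials = 1000L, rng_seed = 1L, output_dir = ".", fast = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML document describing a pipeline run and fills in the
#' reference defaults (small-world topology, `N = 1000`, `k_nn = 4`,
#' `p_rew = 0.05`, `m = 2`, `m0 = 0`, varied-position scheme, 1000 trials).
#' `m0` may be given as the string `"N/2"`. All validation problems are
#' reported together.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` file; an empty document
#'   yields the all-defaults configuration.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @param settings Named list of configuration overrides.
#' @export
as_run_config <- function(settings = list()) {
  defaults <- run_config_defaults()
  problems <- character(0)
  unknown <- setdiff(names(settings), names(defaults))
  if (length(unknown))
    problems <- c(problems, paste0("unknown keys: ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, settings[setdiff(names(settings), unknown)])
  if (identical(cfg$m0, "N/2")) cfg$m0 <- as.integer(cfg$n_nodes) %/% 2L
  if (!cfg$mode %in% c("sweep", "scaling"))
    problems <- c(problems, "mode must be 'sweep' or 'scaling'")
  if (!cfg$topology %in% c("smallworld", "scalefree", "kronecker", "erdosrenyi"))
    problems <- c(problems, "unknown topology")
  if (!cfg$scheme %in% c("varied_position", "fixed_upper"))
    problems <- c(problems, "scheme must be 'varied_position' or 'fixed_upper'")
  if (!is.numeric(cfg$trials) || cfg$trials < 1)
    problems <- c(problems, "trials must be a positive integer")
  if (!is.numeric(cfg$rng_seed))
    problems <- c(problems, "rng_seed must be an integer")
  if (length(problems) == 0) {
    net <- tryCatch({
      net_config(cfg$topology, n_nodes = cfg$n_nodes, k_nn = cfg$k_nn,
                 p_rew = cfg$p_rew, m = cfg$m, m0 = cfg$m0,
                 seed_dim = cfg$seed_dim, seed_zeros = cfg$seed_zeros,
                 power = cfg$power, connectance = cfg$connectance)
    }, netstab_invalid_parameter = function(e) {
      problems <<- c(problems, conditionMessage(e))
      NULL
    })
  }
  if (length(problems))
    stop_invalid(paste0("invalid run configuration:\n  - ",
                        paste(problems, collapse = "\n  - ")))
  cfg$net <- net
  class(cfg) <- "run_config"
  cfg
}

#' Run a configured experiment and write its artifacts
#'
#' Orchestrates the full pipeline for one configuration. In `"sweep"` mode
#' it runs the adaptive self-coupling sweep at the configured size and
#' writes `curve.csv` and `hill.json`; in `"scaling"` mode it runs the
#' size scan and writes `scaling.csv` and `powerlaw.json`. Both modes write
#' `manifest.json` echoing the fully resolved configuration (including the
#' master seed from which all per-trial seeds derive), from which every
#' emitted number is re-derivable. `fast = TRUE` lowers the trial count to
#' `min(trials, 100)`.
#'
#' @param config A `run_config` (see [load_config()]).
#' @return Named list of written file paths, invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- if (isTRUE(config$fast)) min(config$trials, 100L) else config$trials
  out <- list(manifest = file.path(config$output_dir, "manifest.json"))
  write_csv17 <- function(d, path) {
    num <- vapply(d, is.double, logical(1))
    d[num] <- lapply(d[num], fmt17)
    utils::write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  if (config$mode == "sweep") {
    curve <- sweep_auto(config$net, config$scheme, trials, config$rng_seed)
    fit <- fit_hill(curve)
    out$curve <- file.path(config$output_dir, "curve.csv")
    write_csv17(as.data.frame(curve), out$curve)
    out$fit <- file.path(config$output_dir, "hill.json")
    jsonlite::write_json(fit[c("c", "c_err", "n", "n_err", "covariance_cn",
                               "mu", "mu_err", "scheme")],
                         out$fit, auto_unbox = TRUE, digits = NA)
  } else {
    cv <- scaling_curve(config$net, config$sizes, config$scheme,
                        trials, config$rng_seed)
    pl <- fit_power_law(cv)
    out$curve <- file.path(config$output_dir, "scaling.csv")
    write_csv17(data.frame(N = cv$sizes, mu = cv$mu_values,
                           mu_err = cv$mu_errors), out$curve)
    out$fit <- file.path(config$output_dir, "powerlaw.json")
    jsonlite::write_json(pl[c("A", "A_err", "p", "p_err")],
                         out$fit, auto_unbox = TRUE, digits = NA)
  }
  manifest <- unclass(config)
  manifest$net <- NULL
  manifest$resolved_trials <- trials
  manifest$outputs <- lapply(out, basename)
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out)
}
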
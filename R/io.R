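#' Load and validate a run configuration
#'
#' Reads a YAML configuration, applies the package defaults for every
#' missing key and validates all values.  Unknown keys and non-physical
#' values are errors naming the offending key.  An empty file yields the
#' full default configuration: the standard model constants
#' (`epsilon = 0.05` Ha, `x0 = 1` bohr, `Vc = 0.01` Ha, `mass = 1836.15`),
#' `dt = 5` a.t.u., `alpha = 0.9` and `burn_in_fraction = 0.15`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A list of class `natps_config` with elements `model`
#'   (a [two_state_model()]), `tps` (a [tps_config()]) and `seed`
#'   (integer or `NULL`).
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  defaults <- list(epsilon = 0.05, x0 = 1.0, Vc = 0.01, mass = 1836.15,
                   temperature = 12000, alpha = 0.9, dt = 5,
                   n_sub = 32L, root_tol = 1e-10,
                   max_steps_per_side = 4000L, n_paths = 1000L,
                   burn_in_fraction = 0.15,
                   reverse_policy = "reverse-accept", seed = NULL)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, raw)
  check <- function(ok, key, why)
    if (!ok) stop("invalid value for '", key, "': ", why)
  check(cfg$epsilon > 0, "epsilon", "must be > 0")
  check(cfg$x0 > 0, "x0", "must be > 0")
  check(cfg$Vc >= 0, "Vc", "must be >= 0")
  check(cfg$mass > 0, "mass", "must be > 0")
  check(cfg$temperature > 0, "temperature", "must be > 0 kelvin")
  check(cfg$alpha > 0 && cfg$alpha < 1, "alpha", "must lie in (0, 1)")
  check(cfg$dt > 0, "dt", "must be > 0")
  check(cfg$burn_in_fraction >= 0 && cfg$burn_in_fraction < 1,
        "burn_in_fraction", "must lie in [0, 1)")
  check(cfg$n_paths >= 1, "n_paths", "must be >= 1")
  structure(list(
    model = two_state_model(cfg$epsilon, cfg$x0, cfg$Vc, cfg$mass),
    tps = tps_config(temperature = cfg$temperature, alpha = cfg$alpha,
                     n_paths = cfg$n_paths,
                     burn_in_fraction = cfg$burn_in_fraction,
                     dt = cfg$dt, n_sub = cfg$n_sub,
                     root_tol = cfg$root_tol,
                     max_steps_per_side = cfg$max_steps_per_side,
                     reverse_policy = cfg$reverse_policy),
    seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed)),
    class = "natps_config")
}

#' Save a run configuration
#'
#' Writes the flat key-value form read by [load_config()]; the round trip
#' is the identity on all keys.
#'
#' @param config a `natps_config`.
#' @param path output YAML file.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "natps_config"))
  m <- config$model; t <- config$tps
  out <- list(epsilon = m$epsilon, x0 = m$x0, Vc = m$Vc, mass = m$mass,
              temperature = t$temperature, alpha = t$alpha, dt = t$dt,
              n_sub = t$n_sub, root_tol = t$root_tol,
              max_steps_per_side = t$max_steps_per_side,
              n_paths = t$n_paths, burn_in_fraction = t$burn_in_fraction,
              reverse_policy = t$reverse_policy)
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

points_df <- function(points, id) {
  data.frame(path_id = id, t = points[, "t"], q = points[, "q"],
             p = points[, "p"], Sx = points[, "Sx"], Sy = points[, "Sy"],
             Sz = points[, "Sz"], active = points[, "active"])
}

ARCHIVE_FORMAT <- 1L

#' Write a trajectory or ensemble archive
#'
#' Archives are self-describing directories of plain-text tables: a
#' `manifest.yaml` (archive format version, package version, object class,
#' model constants, run configuration), `points.csv` (one row per stored
#' point, keyed by path id), `hops.csv`, and for ensembles `chain.csv` and
#' `records.csv`.  All numeric fields are written at full double precision,
#' so the read round trip is lossless.
#'
#' @param x a `mash_trajectory` or `natps_ensemble` (with stored paths).
#' @param path archive directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_archive <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(archive_format = ARCHIVE_FORMAT,
                   package_version =
                     as.character(utils::packageVersion("natps")),
                   created = format(Sys.time(), tz = "UTC"))
  if (inherits(x, "mash_trajectory")) {
    manifest$class <- "mash_trajectory"
    manifest$dt <- fmt_num(x$dt)
    manifest$status <- x$status
    write_table(points_df(x$points, 1L), file.path(path, "points.csv"))
    write_table(cbind(path_id = 1L, x$hops), file.path(path, "hops.csv"))
  } else if (inherits(x, "natps_ensemble")) {
    if (any(vapply(x$paths, is.null, logical(1))))
      stop("cannot archive an ensemble without stored paths")
    manifest$class <- "natps_ensemble"
    m <- x$model; cfg <- x$config
    manifest$model <- list(epsilon = fmt_num(m$epsilon),
                           x0 = fmt_num(m$x0), Vc = fmt_num(m$Vc),
                           mass = fmt_num(m$mass))
    manifest$tps <- list(temperature = fmt_num(cfg$temperature),
                         alpha = fmt_num(cfg$alpha),
                         n_paths = cfg$n_paths,
                         burn_in_fraction = fmt_num(cfg$burn_in_fraction),
                         dt = fmt_num(cfg$dt), n_sub = cfg$n_sub,
                         root_tol = fmt_num(cfg$root_tol),
                         max_steps_per_side = cfg$max_steps_per_side,
                         reverse_policy = cfg$reverse_policy)
    manifest$basins <- list(
      A = list(q_bound = fmt_num(x$basins$A$q_bound), side = x$basins$A$side),
      B = list(q_bound = fmt_num(x$basins$B$q_bound), side = x$basins$B$side))
    manifest$burn_in <- x$burn_in
    manifest$total_steps <- fmt_num(x$total_steps)
    pts <- do.call(rbind, lapply(seq_along(x$paths), function(i)
      points_df(x$paths[[i]]$points, i)))
    hps <- do.call(rbind, lapply(seq_along(x$paths), function(i)
      if (nrow(x$paths[[i]]$hops)) cbind(path_id = i, x$paths[[i]]$hops)))
    if (is.null(hps))
      hps <- cbind(path_id = integer(), hops_frame(NULL))
    write_table(pts, file.path(path, "points.csv"))
    write_table(hps, file.path(path, "hops.csv"))
    write_table(data.frame(step = seq_along(x$chain), path_id = x$chain),
                file.path(path, "chain.csv"))
    write_table(x$records, file.path(path, "records.csv"))
  } else stop("unsupported object class")
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  invisible(path)
}

read_points <- function(path) {
  df <- utils::read.csv(path)
  num <- setdiff(names(df), c("path_id", "direction", "frustrated",
                              "status"))
  for (j in num) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Read a trajectory or ensemble archive
#'
#' @param path archive directory written by [write_archive()].
#' @return The reconstructed `mash_trajectory` or `natps_ensemble`.
#' @export
read_archive <- function(path) {
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf))
    stop("not an archive (missing manifest.yaml): ", path)
  manifest <- yaml::read_yaml(mf)
  if (is.null(manifest$archive_format) ||
      manifest$archive_format != ARCHIVE_FORMAT)
    stop("archive format version mismatch: found ",
         manifest$archive_format %||% "<none>", ", expected ",
         ARCHIVE_FORMAT)
  pts <- read_points(file.path(path, "points.csv"))
  hps <- read_points(file.path(path, "hops.csv"))
  if (nrow(hps)) hps$frustrated <- hps$frustrated == "TRUE" |
    hps$frustrated == TRUE
  build_traj <- function(id, dt, status = "done") {
    p <- as.matrix(pts[pts$path_id == id,
                       c("t", "q", "p", "Sx", "Sy", "Sz", "active")])
    rownames(p) <- NULL
    h <- hps[hps$path_id == id,
             c("t", "q", "Sx", "Sy", "phi", "direction", "frustrated"),
             drop = FALSE]
    rownames(h) <- NULL
    new_trajectory(p, h, dt, status = status)
  }
  if (manifest$class == "mash_trajectory")
    return(build_traj(1L, as.numeric(manifest$dt),
                      status = manifest$status))
  cfgl <- manifest$tps
  cfg <- tps_config(temperature = as.numeric(cfgl$temperature),
                    alpha = as.numeric(cfgl$alpha),
                    n_paths = cfgl$n_paths,
                    burn_in_fraction = as.numeric(cfgl$burn_in_fraction),
                    dt = as.numeric(cfgl$dt), n_sub = cfgl$n_sub,
                    root_tol = as.numeric(cfgl$root_tol),
                    max_steps_per_side = cfgl$max_steps_per_side,
                    reverse_policy = cfgl$reverse_policy)
  ml <- manifest$model
  model <- two_state_model(as.numeric(ml$epsilon), as.numeric(ml$x0),
                           as.numeric(ml$Vc), as.numeric(ml$mass))
  bl <- manifest$basins
  basins <- list(A = basin_spec("A", as.numeric(bl$A$q_bound), bl$A$side),
                 B = basin_spec("B", as.numeric(bl$B$q_bound), bl$B$side))
  ids <- sort(unique(pts$path_id))
  paths <- lapply(ids, build_traj, dt = as.numeric(cfgl$dt),
                  status = "reactive")
  chain <- utils::read.csv(file.path(path, "chain.csv"))$path_id
  records <- utils::read.csv(file.path(path, "records.csv"))
  records$accepted <- records$accepted == "TRUE" | records$accepted == TRUE
  structure(list(paths = paths,
                 summaries = lapply(paths, path_summary),
                 chain = as.integer(chain),
                 records = records,
                 burn_in = as.integer(manifest$burn_in),
                 total_steps = as.numeric(manifest$total_steps),
                 config = cfg, model = model, basins = basins),
            class = "natps_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
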
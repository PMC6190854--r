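#' @keywords internal
"_PACKAGE"

# locale-independent number formatting: 17 significant digits round-trips
# doubles exactly
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# fixed-order, locale-independent CSV writer ("\n", UTF-8, '.' decimal)
write_table_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) format_num(col)
    else as.character(col)
  })
  header <- paste(names(df), collapse = ",")
  body <- if (nrow(df) > 0L) do.call(paste, c(cols, sep = ",")) else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read / write a contour CSV
#'
#' Contour files have a header row and columns `x,y`, one row per vertex;
#' the closing edge (last vertex back to the first) is implicit.
#'
#' @param path File path.
#' @return `read_contour_csv()` returns a [contour_xy()] object;
#'   `write_contour_csv()` returns the path invisibly.
#' @export
read_contour_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("contour CSV needs columns `x` and `y`", call. = FALSE)
  contour_xy(df$x, df$y)
}

#' @rdname read_contour_csv
#' @param contour A [contour_xy()] object.
#' @export
write_contour_csv <- function(contour, path) {
  contour <- as_contour(contour)
  write_table_csv(data.frame(x = contour$points[, 1L], y = contour$points[, 2L]), path)
}

#' Generate deterministic test fixtures
#'
#' Produces the small geometric objects the model is exercised on. Kinds:
#' \describe{
#'   \item{ring}{A closed ring of `n` cells at unit (or `spacing`) bond
#'     length plus the matching junction table; optional positional `jitter`.}
#'   \item{chain}{An open chain of `n` cells along the x-axis.}
#'   \item{teardrop}{A piriform (teardrop) contour of `n` vertices, the
#'     droplet-stage opening shape.}
#'   \item{ellipse}{An axis-aligned ellipse contour with semi-axes `a`, `b`.}
#' }
#' All output is deterministic for a fixed `seed`.
#'
#' @param kind One of `"ring"`, `"chain"`, `"teardrop"`, `"ellipse"`.
#' @param params Named list of kind-specific parameters (see Details).
#' @param seed Integer seed for the jitter RNG.
#' @return For `ring`/`chain`, a list with `cells` and `junctions` data
#'   frames (CSV schemas `cell_id,x,y,role,column_index` and
#'   `cell_a,cell_b,rest_length,stiffness`); for the contour kinds, a
#'   [contour_xy()] object.
#' @export
make_fixture <- function(kind, params = list(), seed = 1L) {
  kind <- match.arg(kind, c("ring", "chain", "teardrop", "ellipse"))
  p <- function(nm, default) if (!is.null(params[[nm]])) params[[nm]] else default
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))

  if (kind == "ring") {
    n <- as.integer(p("n", 24L))
    if (n < 3L) stop("ring needs n >= 3", call. = FALSE)
    spacing <- p("spacing", 1)
    radius <- p("radius", spacing / (2 * sin(pi / n)))
    stiffness <- p("stiffness", 1)
    jitter <- p("jitter", 0)
    th <- (seq_len(n) - 1L) / n * 2 * pi
    x <- radius * cos(th); y <- radius * sin(th)
    if (jitter > 0) {
      x <- x + stats::rnorm(n, 0, jitter)
      y <- y + stats::rnorm(n, 0, jitter)
    }
    role <- rep("epithelial", n); role[1L] <- "MCE"
    cells <- data.frame(cell_id = seq_len(n), x = x, y = y,
                        role = role, column_index = seq_len(n))
    rest <- p("rest_length", 2 * radius * sin(pi / n))
    junctions <- data.frame(cell_a = seq_len(n),
                            cell_b = c(seq_len(n)[-1L], 1L),
                            rest_length = rest, stiffness = stiffness)
    return(list(cells = cells, junctions = junctions))
  }
  if (kind == "chain") {
    n <- as.integer(p("n", 10L))
    if (n < 2L) stop("chain needs n >= 2", call. = FALSE)
    spacing <- p("spacing", 1)
    stiffness <- p("stiffness", 1)
    cells <- data.frame(cell_id = seq_len(n), x = (seq_len(n) - 1L) * spacing,
                        y = 0, role = rep("epithelial", n),
                        column_index = seq_len(n))
    junctions <- data.frame(cell_a = seq_len(n - 1L), cell_b = 2:n,
                            rest_length = spacing, stiffness = stiffness)
    return(list(cells = cells, junctions = junctions))
  }
  if (kind == "teardrop") {
    n <- as.integer(p("n", 200L))
    scale <- p("scale", 1)
    t <- (seq_len(n) - 0.5) / n * 2 * pi
    # piriform curve: blunt round base with a drawn-out tip
    x <- scale * (1 + sin(t))
    y <- scale * cos(t) * (1 + sin(t)) / 2
    return(contour_xy(x, y))
  }
  # ellipse
  n <- as.integer(p("n", 360L))
  a <- p("a", 1); b <- p("b", 1)
  t <- (seq_len(n) - 1L) / n * 2 * pi
  contour_xy(a * cos(t), b * sin(t))
}

#' Read a simulation configuration file
#'
#' Parses a flat `key = value` text file (one pair per line, `#` comments and
#' blank lines allowed) into a validated [sim_config()]. Keys are exactly the
#' `sim_config()` arguments; `A_L_schedule` is a comma-separated list and
#' `emt_enabled` is `true`/`false`. Unknown keys, duplicate keys and
#' invariant violations are errors naming the key; omitted keys take the
#' documented defaults (a message lists which defaults were applied).
#'
#' @param path Path to the configuration file.
#' @return A [sim_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop(sprintf("config error: malformed line `%s`", lines[bad][1L]), call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  if (anyDuplicated(keys))
    stop(sprintf("config error: duplicate key `%s`", keys[duplicated(keys)][1L]), call. = FALSE)
  allowed <- setdiff(names(formals(sim_config)), character())
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop(sprintf("config error: unknown key `%s`", unknown[1L]), call. = FALSE)

  parse_val <- function(key, val) {
    if (key == "A_L_schedule") {
      v <- as.numeric(trimws(strsplit(val, ",", fixed = TRUE)[[1L]]))
      if (anyNA(v)) stop("config error: invalid value for `A_L_schedule`", call. = FALSE)
      return(v)
    }
    if (key == "emt_enabled") {
      lv <- tolower(val)
      if (!lv %in% c("true", "false")) stop("config error: invalid value for `emt_enabled`", call. = FALSE)
      return(lv == "true")
    }
    v <- suppressWarnings(as.numeric(val))
    if (is.na(v)) stop(sprintf("config error: invalid value for `%s`", key), call. = FALSE)
    v
  }
  args <- stats::setNames(lapply(seq_along(keys), function(i) parse_val(keys[i], vals[i])), keys)
  defaults <- setdiff(allowed, keys)
  if (length(defaults))
    message("applying defaults for: ", paste(sort(defaults), collapse = ", "))
  cfg <- tryCatch(do.call(sim_config, args), error = function(e)
    stop(sprintf("config error: %s", conditionMessage(e)), call. = FALSE))
  cfg
}

canonical_config_text <- function(config) {
  flat <- lapply(config, function(v) paste(format_num(as.numeric(v)), collapse = ","))
  paste(sprintf("%s=%s", names(flat), unlist(flat)), collapse = "\n")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  con <- file(tmp, open = "wb")
  writeLines(canonical_config_text(config), con = con, sep = "\n", useBytes = TRUE)
  close(con)
  unname(tools::md5sum(tmp))
}

# minimal plain-text SVG rendering of one contour
write_contour_svg <- function(contour, path, size = 400) {
  contour <- as_contour(contour)
  pts <- contour$points
  rng <- apply(pts, 2L, range)
  span <- max(rng[2L, ] - rng[1L, ], 1e-12)
  sc <- (size * 0.9) / span
  px <- (pts[, 1L] - rng[1L, 1L]) * sc + size * 0.05
  py <- size - ((pts[, 2L] - rng[1L, 2L]) * sc + size * 0.05)
  pstr <- paste(sprintf("%.3f,%.3f", px, py), collapse = " ")
  svg <- c(sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\">", size, size),
           sprintf("<polygon points=\"%s\" fill=\"none\" stroke=\"black\"/>", pstr),
           "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(svg, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write the artifacts of a simulation run
#'
#' Serializes a [run_crypt_sim()] result into a directory: `trajectory.csv`
#' (`step,F_C_xz,S_x,label,iso_ratio,aspect_ratio,n_emt_events`),
#' `ledger.csv` (`n,F,K_spring,F_v,S_n,S0_n,net,S_x_cumulative`),
#' `emt_events.csv`, `depth.csv` (when a depth profile exists), optional
#' per-checkpoint contour SVGs, and a `manifest.json` recording the config
#' snapshot, seed, package version, a provenance hash of the canonicalized
#' inputs, and every file written. Numbers are written with 17 significant
#' digits so re-reading reproduces the run bit-identically.
#'
#' @param sim A `crypt_sim` object.
#' @param out_dir Output directory (created if needed).
#' @param svg Also write per-checkpoint contour SVGs.
#' @return The manifest, invisibly (class `run_manifest`).
#' @export
write_outputs <- function(sim, out_dir, svg = FALSE) {
  stopifnot(inherits(sim, "crypt_sim"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  }
  files <- list()
  f <- function(name) file.path(out_dir, name)
  write_table_csv(sim$trajectory, f("trajectory.csv")); files$trajectory <- f("trajectory.csv")
  write_table_csv(as.data.frame(sim$ledger), f("ledger.csv")); files$ledger <- f("ledger.csv")
  write_table_csv(sim$emt_events, f("emt_events.csv")); files$emt_events <- f("emt_events.csv")
  if (!is.null(sim$depth)) {
    write_table_csv(sim$depth, f("depth.csv")); files$depth <- f("depth.csv")
  }
  if (isTRUE(svg)) {
    for (nm in names(sim$contours)) {
      path <- f(sprintf("contour_step_%s.svg", nm))
      write_contour_svg(sim$contours[[nm]], path)
      files[[sprintf("contour_step_%s", nm)]] <- path
    }
  }
  manifest <- structure(list(
    package = "cryptmech",
    version = as.character(utils::packageVersion("cryptmech")),
    seed = sim$config$seed,
    config = unclass(sim$config),
    input_hash = config_hash(sim$config),
    files = lapply(files, basename)
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), f("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$manifest <- f("manifest.json")
  invisible(manifest)
}

#' Read back a trajectory CSV
#'
#' Inverse of the trajectory writer in [write_outputs()].
#'
#' @param path Path to `trajectory.csv`.
#' @return Data frame with the trajectory columns.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  utils::read.csv(path, colClasses = c(step = "integer", F_C_xz = "numeric",
                                       S_x = "numeric", label = "character",
                                       iso_ratio = "numeric",
                                       aspect_ratio = "numeric",
                                       n_emt_events = "integer"))
}
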
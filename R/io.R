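#' Load a dyad dataset from delimited text files
#'
#' Reads a county table (`id,lat,lon,population`), a directed dyad table
#' (`src,dst,count`) and optionally a square distance matrix (km; first
#' column and header row are location ids) and assembles a validated
#' [dyad_data] object. Distances come from the matrix when supplied,
#' otherwise from haversine on the coordinates. Zero-count dyads are
#' dropped with a warning carrying the dropped count.
#'
#' @param county_path path to the county CSV.
#' @param dyad_path path to the dyad CSV.
#' @param distance_path optional path to a distance-matrix CSV.
#' @return a [dyad_data] object.
#' @export
load_dataset <- function(county_path, dyad_path, distance_path = NULL) {
  counties <- utils::read.csv(county_path, stringsAsFactors = FALSE)
  dyads <- utils::read.csv(dyad_path, stringsAsFactors = FALSE)
  dist <- NULL
  if (!is.null(distance_path)) {
    raw <- utils::read.csv(distance_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    ids <- as.character(raw[[1]])
    dist <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(dist) <- "double"
    rownames(dist) <- ids
    colnames(dist) <- as.character(colnames(raw)[-1])
  }
  dyad_data(counties, dyads, dist = dist)
}

#' Write a dyad dataset to delimited text files
#'
#' Inverse of [load_dataset]: writes the county table, the dyad table and
#' the full distance matrix as CSVs.
#'
#' @param data a [dyad_data] object.
#' @param county_path,dyad_path,distance_path output paths;
#'   `distance_path = NULL` skips the matrix.
#' @return `data`, invisibly.
#' @export
write_dataset <- function(data, county_path, dyad_path,
                          distance_path = NULL) {
  loc <- data$locations
  keep <- intersect(c("id", "lat", "lon", "population"), names(loc))
  utils::write.csv(loc[, keep, drop = FALSE], county_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data$pairs[, c("src", "dst", "count")], dyad_path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(distance_path)) {
    m <- data.frame(id = rownames(data$dist), data$dist,
                    check.names = FALSE)
    utils::write.csv(m, distance_path, row.names = FALSE, quote = FALSE)
  }
  invisible(data)
}

DRAWS_SCHEMA <- "gravbreak-draws-v1"

#' Write posterior draws to a delimited text file
#'
#' One row per retained outer iteration; columns cover every monitored
#' quantity (theta_i, beta4_i, beta3_i, eta_i and acceptance indicator
#' per source, global coefficients, sigma2, lambda2, boundary count and
#' the model label). The first line is a schema-version header so that
#' [read_draws] can refuse files written by an incompatible version.
#'
#' @param draws a `cp_draws` object from [run_case1] or [run_case2].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "cp_draws"))
  tab <- draws_to_table(draws)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", DRAWS_SCHEMA, " case=", draws$case,
                    " S=", draws$S), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

draws_to_table <- function(draws) {
  S <- draws$S
  tab <- data.frame(iter = seq_len(nrow(draws$theta)))
  add <- function(tab, m, prefix) {
    colnames(m) <- paste0(prefix, "_", seq_len(ncol(m)))
    cbind(tab, m)
  }
  tab <- add(tab, draws$theta, "theta")
  tab <- add(tab, draws$beta3, "beta3")
  tab <- add(tab, draws$beta4, "beta4")
  tab <- add(tab, draws$eta, "eta")
  tab <- add(tab, draws$accept, "accept")
  tab$mu <- draws$mu
  tab$beta1 <- draws$beta1
  tab$beta2 <- draws$beta2
  if (draws$case == "II") {
    tab$mu_cp <- draws$mu_cp
    tab$beta1_cp <- draws$beta1_cp
    tab$beta2_cp <- draws$beta2_cp
  }
  tab$sigma2 <- draws$sigma2
  tab$lambda2 <- draws$lambda2
  tab$b <- draws$b
  tab$p_cols <- draws$p_cols
  tab$model <- draws$model
  tab
}

#' Read posterior draws written by [write_draws]
#'
#' @param path path to a draws CSV.
#' @return a `cp_draws` object with all monitored fields restored.
#' @export
read_draws <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, paste0("# ", DRAWS_SCHEMA)))
    stop("not a ", DRAWS_SCHEMA, " file: ", path)
  meta <- strsplit(sub("^# *", "", header), " +")[[1]]
  kv <- strsplit(meta[-1], "=")
  opts <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  case <- opts[["case"]]
  S <- as.integer(opts[["S"]])
  tab <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)

  grab <- function(prefix) {
    cols <- paste0(prefix, "_", seq_len(S))
    missing <- setdiff(cols, names(tab))
    if (length(missing))
      stop("draws file missing column(s): ", paste(missing, collapse = ", "))
    as.matrix(tab[, cols, drop = FALSE])
  }
  need <- function(col) {
    if (!col %in% names(tab)) stop("draws file missing column(s): ", col)
    tab[[col]]
  }
  draws <- list(
    theta = grab("theta"), beta3 = grab("beta3"), beta4 = grab("beta4"),
    eta = grab("eta"), accept = grab("accept"),
    mu = need("mu"), beta1 = need("beta1"), beta2 = need("beta2"),
    sigma2 = need("sigma2"), lambda2 = need("lambda2"),
    b = need("b"), p_cols = need("p_cols"),
    model = as.character(need("model")),
    S = S, case = case
  )
  if (case == "II") {
    draws$mu_cp <- need("mu_cp")
    draws$beta1_cp <- need("beta1_cp")
    draws$beta2_cp <- need("beta2_cp")
  }
  class(draws) <- "cp_draws"
  draws
}
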
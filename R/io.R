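# Readers and writers for the package's serialised artifacts: datasets
# (CSV), networks (edge-list TSV + JSON sidecar), score maps (TSV with
# provenance header), and run configuration (YAML).

#' Read a dataset from CSV
#'
#' Expects a header row and a fully numeric body; missing values,
#' non-numeric cells and duplicate headers are rejected with the offending
#' location.
#'
#' @param path CSV file path.
#' @return A numeric matrix with variable column names.
#' @export
readDataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicate column header in ", path, ": ",
         names(df)[duplicated(names(df))][1L])
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) & !is.na(df[[j]]))
      stop(sprintf("non-numeric cell in column '%s'%s of %s", names(df)[j],
                   if (length(bad)) sprintf(", row %d", bad[1L]) else "", path))
    }
  }
  m <- as.matrix(df)
  .checkDataset(m, paste0("dataset '", path, "'"))
}

#' Write a dataset to CSV
#'
#' @param d dataset (numeric matrix or data frame with named columns).
#' @param path output file path.
#' @export
writeDataset <- function(d, path) {
  d <- .checkDataset(d)
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}

#' Write a linear-Gaussian network to disk
#'
#' Writes an edge-list TSV (\code{<base>.edges.tsv}: tail, head,
#' coefficient) and a JSON sidecar (\code{<base>.json}: variables, noise
#' standard deviations, and any metadata supplied).
#'
#' @param net a [LinearGaussianNetwork-class].
#' @param base path prefix (without extension).
#' @param metadata optional named list stored in the sidecar.
#' @export
writeNetwork <- function(net, base, metadata = list()) {
  stopifnot(is(net, "LinearGaussianNetwork"))
  utils::write.table(edgeTable(net), paste0(base, ".edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(variables = variables(net),
               noiseSd = as.numeric(noiseSd(net)),
               topoOrder = net@dag@topoOrder,
               metadata = metadata)
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' Read a network written by [writeNetwork()]
#'
#' @param base path prefix used at write time.
#' @return A [LinearGaussianNetwork-class]; the sidecar metadata is
#'   attached as the \code{"metadata"} attribute.
#' @export
readNetwork <- function(base) {
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  et <- utils::read.delim(paste0(base, ".edges.tsv"), stringsAsFactors = FALSE)
  dag <- CausalDag(side$variables,
                   cbind(match(et$tail, side$variables),
                         match(et$head, side$variables)),
                   topoOrder = as.integer(side$topoOrder))
  net <- LinearGaussianNetwork(dag, et$coefficient, side$noiseSd)
  attr(net, "metadata") <- side$metadata
  net
}

# Shared TSV writer for per-pair matrices, with provenance in header
# comments.
.writePairTsv <- function(m, mode, path, header) {
  vars <- rownames(m)
  rows <- character(0)
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (i == j) next
      if (mode == "skeleton" && i > j) next
      if (m[i, j] == 0) next
      rows <- c(rows, paste(vars[i], vars[j],
                            format(m[i, j], digits = 15), sep = "\t"))
    }
  }
  writeLines(c(paste0("# ", names(header), ": ", unlist(header)),
               paste0("# variables: ", paste(vars, collapse = ",")),
               paste("node1", "node2", "score", sep = "\t"), rows), path)
}

.readPairTsv <- function(path) {
  lines <- readLines(path)
  comments <- grep("^# ", lines, value = TRUE)
  header <- list()
  for (cm in comments) {
    kv <- sub("^# ", "", cm)
    key <- sub(":.*$", "", kv)
    header[[key]] <- sub("^[^:]*: ", "", kv)
  }
  vars <- strsplit(header$variables, ",")[[1L]]
  body <- lines[!grepl("^#", lines)]
  p <- length(vars)
  m <- matrix(0, p, p, dimnames = list(vars, vars))
  if (length(body) > 1L) {
    tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(tab))) {
      i <- match(tab$node1[k], vars)
      j <- match(tab$node2[k], vars)
      m[i, j] <- tab$score[k]
      if (identical(header$mode, "skeleton")) m[j, i] <- tab$score[k]
    }
  }
  list(m = m, header = header)
}

#' Write an edge-frequency or diff-score map to TSV
#'
#' Zero-score pairs are omitted; header comments record the class, mode,
#' method/B, and any extra provenance fields supplied.
#'
#' @param map an [EdgeScoreMap-class] or [DiffScoreMap-class].
#' @param path output file path.
#' @param provenance optional named list of extra header fields (seed,
#'   algorithm, params, policies).
#' @export
writeScoreMap <- function(map, path, provenance = list()) {
  if (is(map, "EdgeScoreMap")) {
    header <- c(list(class = "EdgeScoreMap", mode = map@mode, B = map@B),
                provenance)
    .writePairTsv(map@scores, map@mode, path, header)
  } else if (is(map, "DiffScoreMap")) {
    header <- c(list(class = "DiffScoreMap", mode = map@mode,
                     method = map@method,
                     direction = paste(map@direction, collapse = "-")),
                provenance)
    .writePairTsv(map@scores, map@mode, path, header)
  } else {
    stop("map must be an EdgeScoreMap or DiffScoreMap")
  }
  invisible(path)
}

#' Read a score map written by [writeScoreMap()]
#'
#' @param path file path.
#' @return An [EdgeScoreMap-class] or [DiffScoreMap-class], per the file's
#'   class header.
#' @export
readScoreMap <- function(path) {
  parsed <- .readPairTsv(path)
  h <- parsed$header
  if (identical(h$class, "EdgeScoreMap")) {
    EdgeScoreMap(h$mode, parsed$m, as.integer(h$B))
  } else if (identical(h$class, "DiffScoreMap")) {
    DiffScoreMap(h$mode, h$method, parsed$m,
                 strsplit(h$direction, "-")[[1L]])
  } else {
    stop("unrecognised score map class in ", path)
  }
}

#' Default run configuration
#'
#' All tunables in one documented list: discovery backend and settings,
#' estimator list, resample count B, evaluation modes, undirected-edge
#' policy, cross-entropy mapping, and master seed.
#'
#' @return A named list.
#' @export
defaultRunConfig <- function() {
  list(algorithm = "pc",
       params = list(alpha = 0.05, penaltyDiscount = 1),
       methods = c("naive", "bs", "rsbs"),
       B = 50,
       modes = c("orientation", "skeleton"),
       undirectedPolicy = "both",
       ceMapping = "clip",
       seed = 1)
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [defaultRunConfig()], so a config round-trips losslessly.
#'
#' @param path YAML file path.
#' @param config named list (for writing).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(base, cfg)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
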
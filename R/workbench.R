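#' Write a correlation result to CSV
#'
#' Region-labelled symmetric r and p matrices, one file each.
#'
#' @param corr a `correlation_result`.
#' @param r_path,p_path output CSV paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_correlation <- function(corr, r_path = NULL, p_path = NULL) {
  stopifnot(inherits(corr, "correlation_result"))
  written <- character(0)
  write_mat <- function(m, path) {
    df <- data.frame(region = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  if (!is.null(r_path)) written <- c(written, write_mat(corr$r, r_path))
  if (!is.null(p_path)) written <- c(written, write_mat(corr$p, p_path))
  invisible(written)
}

#' Write a network to disk
#'
#' Adjacency CSV (region-labelled), edge-list TSV (`region_a`, `region_b`,
#' plus `r`, `p`, `sign` when a correlation result is supplied) and/or
#' GraphML for external network viewers.
#'
#' @param net an `fc_network`.
#' @param adjacency_csv,edgelist_tsv,graphml output paths; `NULL` skips.
#' @param corr optional `correlation_result` for edge annotation.
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, adjacency_csv = NULL, edgelist_tsv = NULL,
                          graphml = NULL, corr = NULL) {
  stopifnot(inherits(net, "fc_network"))
  written <- character(0)
  if (!is.null(adjacency_csv)) {
    df <- data.frame(region = net$regions, net$adjacency, check.names = FALSE)
    utils::write.csv(df, adjacency_csv, row.names = FALSE, quote = FALSE)
    written <- c(written, adjacency_csv)
  }
  if (!is.null(edgelist_tsv)) {
    utils::write.table(edge_list(net, corr), edgelist_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, edgelist_tsv)
  }
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(net), graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}

#' Write a metrics report
#'
#' JSON (global scalars plus per-region arrays keyed by label) and tidy CSV
#' (one row per region).
#'
#' @param report a [network_metrics()] report.
#' @param json_path,csv_path output paths; `NULL` skips.
#' @return invisibly, the paths written.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  written <- character(0)
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(metrics_table(report), csv_path, row.names = FALSE,
                     quote = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}

#' Write a stability report
#'
#' Tidy CSVs: per-edge rows `(region_a, region_b, size, flip_rate,
#' p_variance, class)` and per-size rows `(size, aggregate_variance,
#' n_combinations)`, plus an optional JSON bundle of the whole report.
#'
#' @param report a [subsample_scan()] result.
#' @param edges_csv,sizes_csv,json_path output paths; `NULL` skips.
#' @return invisibly, the paths written.
#' @export
write_stability <- function(report, edges_csv = NULL, sizes_csv = NULL,
                            json_path = NULL) {
  stopifnot(inherits(report, "stability_report"))
  written <- character(0)
  if (!is.null(edges_csv)) {
    long <- do.call(rbind, lapply(seq_along(report$sizes), function(si) {
      data.frame(region_a = report$edges$region_a,
                 region_b = report$edges$region_b,
                 size = report$sizes[si],
                 flip_rate = report$flip_rate[, si],
                 p_variance = report$p_variance[, si],
                 class = report$edges$class,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, edges_csv, row.names = FALSE, quote = FALSE)
    written <- c(written, edges_csv)
  }
  if (!is.null(sizes_csv)) {
    df <- data.frame(size = report$sizes,
                     aggregate_variance = unname(report$variance_by_size),
                     n_combinations = unname(report$n_combinations))
    utils::write.csv(df, sizes_csv, row.names = FALSE, quote = FALSE)
    written <- c(written, sizes_csv)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, json_path)
  }
  invisible(written)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers where possible, `true`/`false` as logicals, comma-separated
#' lists as vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!any(is.na(num))) num
    else if (all(tolower(parts) %in% c("true", "false"))) tolower(parts) == "true"
    else parts
    out[[key]] <- parsed
  }
  out
}

#' Run the full analysis pipeline
#'
#' Ingest -> correlate -> threshold -> metrics (and optionally the group-size
#' stability scan), writing every artifact plus a JSON provenance sidecar
#' (configuration echo, package and R versions, seeds, input checksum)
#' sufficient to reproduce the run bit-exactly. Any stage failure aborts with
#' the stage named.
#'
#' @param input path to a region-by-animal CSV, or a [region_table()].
#' @param output_dir directory for artifacts (created if needed).
#' @param spec a [threshold_spec()].
#' @param stability_sizes optional integer vector of subgroup sizes; when
#'   given, [subsample_scan()] runs and its reports are written too.
#' @param sigma compute the small-world coefficient in the metrics report.
#' @param seed seed for the null models / Monte-Carlo components.
#' @param n_null null-ensemble size when `sigma = TRUE`.
#' @return invisibly, a list with the in-memory results (`table`, `corr`,
#'   `network`, `metrics`, `stability`) and `files` (all paths written).
#' @export
run_pipeline <- function(input, output_dir, spec = threshold_spec(),
                         stability_sizes = NULL, sigma = FALSE, seed = 1L,
                         n_null = 100L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(output_dir, f)

  input_path <- NULL
  table <- stage("ingest", {
    if (is.character(input)) {
      input_path <- input
      load_region_table(input)
    } else {
      as_region_table(input)
    }
  })
  corr <- stage("correlate", correlate_table(table))
  net <- stage("threshold", binarize(corr, spec))
  metrics <- stage("metrics",
                   network_metrics(net, sigma = sigma, seed = seed,
                                   n_null = n_null))
  stab <- NULL
  if (!is.null(stability_sizes)) {
    stab <- stage("stability",
                  subsample_scan(table, sizes = stability_sizes, spec = spec,
                                 mc_seed = seed))
  }

  files <- c(
    stage("write", {
      write_region_table(table, out("region_table.csv"))
      write_correlation(corr, out("correlation_r.csv"), out("correlation_p.csv"))
      write_network(net, out("adjacency.csv"), out("edges.tsv"),
                    out("network.graphml"), corr = corr)
      write_metrics(metrics, out("metrics.json"), out("metrics.csv"))
      if (!is.null(stab)) {
        write_stability(stab, out("stability_edges.csv"),
                        out("stability_sizes.csv"))
      }
      list.files(output_dir, full.names = TRUE)
    })
  )

  provenance <- list(
    package = "iegnet",
    version = as.character(utils::packageVersion("iegnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = NULL,  # deliberately omitted: outputs must be bit-reproducible
    input = if (!is.null(input_path)) {
      list(path = input_path, md5 = unname(tools::md5sum(input_path)))
    } else "in-memory region_table",
    threshold = list(alpha = spec$alpha, fdr_q = spec$fdr_q,
                     r_min = spec$r_min, sign_policy = spec$sign_policy),
    stability_sizes = stability_sizes,
    sigma = sigma, seed = seed, n_null = n_null,
    n_regions = nrow(table), n_animals = ncol(table))
  jsonlite::write_json(provenance, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(table = table, corr = corr, network = net, metrics = metrics,
                 stability = stab,
                 files = sort(list.files(output_dir, full.names = TRUE))))
}
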
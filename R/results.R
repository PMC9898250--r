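# Tabular results: long-format metric tables with explicit units, and
# replica aggregation treating each replica as an independent sample.

#' Build a long-format result table
#'
#' @param system system label.
#' @param replica replica id.
#' @param frame frame or window index (may be `NA` for per-replica
#'   scalars).
#' @param metric metric name.
#' @param value numeric value.
#' @param unit unit string.
#' @return data.frame with those columns.
#' @export
result_table <- function(system, replica, frame, metric, value, unit) {
  data.frame(system = system, replica = replica, frame = frame,
             metric = metric, value = value, unit = unit,
             stringsAsFactors = FALSE)
}

#' Aggregate a result table across replicas
#'
#' Replica means are computed first, then summarised: n is the number of
#' replicas and sd the standard deviation over replica means, never over
#' pooled frames.
#'
#' @param tab a [result_table()]-style data.frame.
#' @return data.frame with `system`, `metric`, `unit`, `n`, `mean`, `sd`.
#' @export
aggregate_replicas <- function(tab) {
  per_rep <- stats::aggregate(value ~ system + metric + unit + replica,
                              data = tab, FUN = mean)
  agg <- stats::aggregate(value ~ system + metric + unit, data = per_rep,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- cbind(agg[, c("system", "metric", "unit")],
               as.data.frame(agg$value))
  names(out)[4:6] <- c("n", "mean", "sd")
  out
}

#' Write a tab-separated result table
#' @param tab data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated result table
#' @param path file path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
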
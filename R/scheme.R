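# Selection schemes: named residue groups that power every descriptor and
# network-node definition. Stored as YAML so per-system residue lists stay
# editable rather than hard-coded.
#
# The two transmembrane-helix half-groupings follow the standard ABC
# descriptor definitions: the intracellular opening uses halves
# {TMH1,2,3,6,10,11} vs {TMH4,5,7,8,9,12}; the extracellular opening uses
# {TMH1,2,9,10,11,12} vs {TMH3,4,5,6,7,8}.

IC_HALF_A <- c(1, 2, 3, 6, 10, 11)
IC_HALF_B <- c(4, 5, 7, 8, 9, 12)
EC_HALF_A <- c(1, 2, 9, 10, 11, 12)
EC_HALF_B <- c(3, 4, 5, 6, 7, 8)

expand_range_spec <- function(x, name) {
  if (is.numeric(x)) return(as.integer(x))
  if (is.list(x)) return(unlist(lapply(x, expand_range_spec, name = name)))
  if (!is.character(x)) stop("config error: group '", name, "' has class ",
                             class(x)[1])
  out <- integer(0)
  for (tok in unlist(strsplit(x, ","))) {
    tok <- trimws(tok)
    if (tok == "") next
    if (grepl("^-?[0-9]+\\s*-\\s*-?[0-9]+$", tok) && !grepl("^-?[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, "(?<=[0-9])\\s*-\\s*", perl = TRUE)[[1]])
      if (length(ab) != 2 || anyNA(ab))
        stop("config error: bad range '", tok, "' in group '", name, "'")
      if (ab[1] > ab[2])
        stop("config error: reversed range '", tok, "' in group '", name, "'")
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^-?[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    } else {
      stop("config error: cannot parse '", tok, "' in group '", name, "'")
    }
  }
  out
}

#' Parse a selection scheme
#'
#' Reads a YAML mapping of group names to residue ranges (e.g. `"5-16"`,
#' `"5-16, 40, 52-60"` or explicit lists) and expands them to residue-id
#' sets. Composite groups needed by the descriptors (`ic_half_a/b`,
#' `ec_half_a/b`, `ec_whole`, `nbd_both`) are derived automatically from
#' per-helix groups `tmh<k>_ic` / `tmh<k>_ec` and `nbd1`/`nbd2` when not
#' given explicitly.
#'
#' @param x path to a YAML file, or a named list already in memory.
#' @return object of class `abc_scheme`: a named list of integer residue-id
#'   vectors.
#' @export
parse_selection_scheme <- function(x) {
  raw <- if (is.character(x) && length(x) == 1) yaml::read_yaml(x) else x
  if (!is.list(raw) || is.null(names(raw)))
    stop("config error: scheme must be a named mapping")
  groups <- lapply(names(raw), function(nm)
    sort(unique(expand_range_spec(raw[[nm]], nm))))
  names(groups) <- names(raw)
  groups <- derive_composite_groups(groups)
  structure(groups, class = "abc_scheme")
}

derive_composite_groups <- function(g) {
  tmh_ic <- paste0("tmh", 1:12, "_ic")
  tmh_ec <- paste0("tmh", 1:12, "_ec")
  if (all(tmh_ic %in% names(g))) {
    if (is.null(g$ic_half_a))
      g$ic_half_a <- sort(unique(unlist(g[paste0("tmh", IC_HALF_A, "_ic")])))
    if (is.null(g$ic_half_b))
      g$ic_half_b <- sort(unique(unlist(g[paste0("tmh", IC_HALF_B, "_ic")])))
  }
  if (all(tmh_ec %in% names(g))) {
    if (is.null(g$ec_half_a))
      g$ec_half_a <- sort(unique(unlist(g[paste0("tmh", EC_HALF_A, "_ec")])))
    if (is.null(g$ec_half_b))
      g$ec_half_b <- sort(unique(unlist(g[paste0("tmh", EC_HALF_B, "_ec")])))
    if (is.null(g$ec_whole))
      g$ec_whole <- sort(unique(unlist(g[tmh_ec])))
  }
  if (!is.null(g$nbd1) && !is.null(g$nbd2) && is.null(g$nbd_both))
    g$nbd_both <- sort(unique(c(g$nbd1, g$nbd2)))
  g
}

#' Validate a scheme against a topology
#'
#' @param scheme an `abc_scheme`.
#' @param top an `abc_topology`.
#' @param required character vector of group names that must be present and
#'   non-empty.
#' @return the scheme, invisibly; stops with the offending ids/groups
#'   otherwise.
#' @export
validate_scheme <- function(scheme, top, required = NULL) {
  have <- residues(top)$res_id
  for (nm in names(scheme)) {
    bad <- setdiff(scheme[[nm]], have)
    if (length(bad))
      stop("validation error: group '", nm, "' references residues absent ",
           "from topology: ", paste(bad, collapse = ", "))
  }
  if (!is.null(scheme$ic_half_a) && !is.null(scheme$ic_half_b) &&
      length(intersect(scheme$ic_half_a, scheme$ic_half_b)))
    stop("validation error: IC half-groups overlap")
  if (!is.null(scheme$ec_half_a) && !is.null(scheme$ec_half_b) &&
      length(intersect(scheme$ec_half_a, scheme$ec_half_b)))
    stop("validation error: EC half-groups overlap")
  for (nm in required) {
    if (is.null(scheme[[nm]]) || !length(scheme[[nm]]))
      stop("config error: required group '", nm, "' missing or empty")
  }
  invisible(scheme)
}

#' Fetch a scheme group or fail with a clear message
#' @param scheme an `abc_scheme`.
#' @param name group name.
#' @return integer residue ids.
#' @export
scheme_group <- function(scheme, name) {
  g <- scheme[[name]]
  if (is.null(g) || !length(g))
    stop("config error: scheme group '", name, "' missing or empty")
  g
}

#' Write a scheme to YAML
#' @param scheme an `abc_scheme` or named list of residue-id vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  compress <- function(v) {
    v <- sort(unique(as.integer(v)))
    br <- c(0, which(diff(v) != 1), length(v))
    paste(vapply(seq_len(length(br) - 1), function(i) {
      a <- v[br[i] + 1]; b <- v[br[i + 1]]
      if (a == b) as.character(a) else paste0(a, "-", b)
    }, character(1)), collapse = ", ")
  }
  out <- lapply(unclass(scheme), compress)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.abc_scheme <- function(x, ...) {
  cat("abc_scheme with", length(x), "groups:\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %d residues\n", nm, length(x[[nm]])))
  invisible(x)
}
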
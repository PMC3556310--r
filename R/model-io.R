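#' @title Reading and writing models and flux states
#' @name model_io
#' @description
#' Models are read from a tab-separated dialect with one reaction per line,
#' `id<TAB>group<TAB>equation` (optionally a fourth column with a free-text
#' name). Equations use `"a A + b B -> c C"` with `"<->"` marking reversible
#' reactions; coefficients default to 1; either side may be empty, which
#' marks an exchange reaction crossing the system boundary. Flux states are
#' read from a two-column TSV `reaction_id<TAB>flux`. JSON equivalents are
#' supported for provenance round-trips.
NULL

parse_equation <- function(eq, where = "") {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- if (rev) strsplit(eq, "<->", fixed = TRUE)[[1]]
           else strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2L || (!rev && !grepl("->", eq, fixed = TRUE))) {
    stop("malformed equation", where, ": '", eq, "'")
  }
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) stop("malformed equation", where, ": '", eq, "'")
      tok <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(tok) == 1L) {
        coef <- 1; met <- tok
      } else if (length(tok) == 2L && !is.na(suppressWarnings(as.numeric(tok[1])))) {
        coef <- as.numeric(tok[1]); met <- tok[2]
      } else {
        stop("malformed term '", tm, "' in equation", where, ": '", eq, "'")
      }
      if (coef <= 0) stop("non-positive coefficient in equation", where, ": '", eq, "'")
      out[met] <- if (met %in% names(out)) out[met] + sign * coef else sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  if (length(lhs) + length(rhs) == 0L) {
    stop("empty equation", where, ": '", eq, "'")
  }
  both <- intersect(names(lhs), names(rhs))
  if (length(both) > 0L) {
    stop("metabolite(s) on both sides of equation", where, ": ",
         paste(both, collapse = ", "))
  }
  list(stoich = c(lhs, rhs), reversible = rev)
}

#' Load a metabolic model from TSV or JSON
#'
#' @param path file path.
#' @param format `"tsv"` (default, dialect above) or `"json"` as written by
#'   [write_model()].
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    rxns <- lapply(obj$reactions, function(r) {
      list(id = r$id, name = r$name, group = r$group,
           stoich = unlist(r$stoich), reversible = isTRUE(r$reversible))
    })
    return(metabolic_model(rxns, exchanges = unlist(obj$exchanges)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("model file is empty: ", path)
  rxns <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("line ", k, " of ", path,
           ": expected id<TAB>group<TAB>equation, got '", lines[k], "'")
    }
    pe <- parse_equation(f[3], where = paste0(" at line ", k))
    rxns[[k]] <- list(id = trimws(f[1]), group = trimws(f[2]),
                      name = if (length(f) >= 4L) trimws(f[4]) else NULL,
                      stoich = pe$stoich, reversible = pe$reversible)
  }
  metabolic_model(rxns)
}

format_equation <- function(stoich, reversible) {
  side <- function(s) {
    if (length(s) == 0L) return("")
    paste(vapply(names(s), function(m) {
      if (abs(s[[m]]) == 1) m else paste(format(abs(s[[m]])), m)
    }, character(1)), collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste0(side(lhs), if (length(lhs)) " " else "",
         if (reversible) "<->" else "->",
         if (length(rhs)) " " else "", side(rhs))
}

#' Write a metabolic model to TSV or JSON
#'
#' The TSV output round-trips through [load_model()] field by field.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "metabolic_model"))
  if (format == "json") {
    obj <- list(
      reactions = lapply(seq_len(nrow(model$reactions)), function(k) {
        rid <- model$reactions$id[k]
        list(id = rid, name = model$reactions$name[k],
             group = model$reactions$group[k],
             reversible = model$reactions$reversible[k],
             stoich = as.list(model$stoich[[rid]]))
      }),
      exchanges = model$exchanges
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nrow(model$reactions)), function(k) {
    rid <- model$reactions$id[k]
    paste(rid, model$reactions$group[k],
          format_equation(model$stoich[[rid]], model$reactions$reversible[k]),
          model$reactions$name[k], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a flux state from TSV
#'
#' Expects a two-column file `reaction_id<TAB>flux` (a header line is
#' detected and skipped). Every model reaction must be present; negative
#' fluxes are only admitted on reversible reactions (they are canonicalized
#' away later by [canonicalize_directions()]).
#'
#' @param path file path.
#' @param model a [metabolic_model()].
#' @param label state name.
#' @param zero_tol numeric floor treated as zero flux.
#' @return a [flux_state()].
#' @export
load_flux_state <- function(path, model, label = basename(path),
                            zero_tol = 1e-9) {
  if (!file.exists(path)) stop("flux file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("flux file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields[[1]]) >= 2L &&
      is.na(suppressWarnings(as.numeric(fields[[1]][2])))) {
    fields <- fields[-1]  # header
  }
  if (length(fields) == 0L) stop("flux file has no data rows: ", path)
  ids <- vapply(fields, `[`, character(1), 1)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  if (anyNA(vals)) {
    stop("non-numeric flux value(s) in ", path, " for: ",
         paste(ids[is.na(vals)], collapse = ", "))
  }
  v <- stats::setNames(vals, trimws(ids))
  flux_state(v, model, label = label, zero_tol = zero_tol)
}

#' Write a flux state to TSV
#'
#' @param state a [flux_state()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flux_state <- function(state, path) {
  stopifnot(inherits(state, "flux_state"))
  utils::write.table(
    data.frame(reaction_id = names(state$v), flux = unname(state$v)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
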
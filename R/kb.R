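# Knowledge base: declarative guideline flowcharts per diagnosis plus
# per-drug dose rule tables. The YAML/JSON schema (inst/extdata/kb-schema.md)
# is normative; loading resolves structure, validate_kb() checks semantics.

#' Load a guideline knowledge base from YAML or JSON
#'
#' Parses a knowledge-base file into an immutable `empirx_kb` object.
#' Structural problems (unknown node kinds, edges pointing at undefined
#' nodes, malformed regimens) are load-time errors naming the offending
#' path; semantic rules are checked separately by [validate_kb()].
#'
#' @param source path to a `.yaml`/`.yml` or `.json` knowledge-base file.
#' @return an object of class `empirx_kb` with elements `version`,
#'   `diagnoses` (named list of pathways) and `dose_rules` (named list of
#'   per-drug dose tables).
#' @seealso [validate_kb()], [enumerate_paths()], [load_example_kb()]
#' @export
load_kb <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (!file.exists(source)) stop("knowledge base file not found: ", source)
  raw <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
    jsonlite::read_json(source, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(source)
  }
  kb_from_list(raw, source = source)
}

#' Build a knowledge base from a parsed list
#'
#' The list mirrors the file schema; useful for constructing knowledge bases
#' in code (the example knowledge base is built this way).
#'
#' @param x nested list following the knowledge-base schema.
#' @param source label used in error messages.
#' @return an `empirx_kb` object.
#' @export
kb_from_list <- function(x, source = "<list>") {
  fail <- function(path, msg)
    stop(sprintf("%s: %s: %s", source, path, msg), call. = FALSE)
  if (!is.list(x)) fail("(top level)", "must be a mapping")
  dx <- x$diagnoses
  if (is.null(dx) || !length(dx) || is.null(names(dx)))
    fail("diagnoses", "must be a non-empty named mapping of pathways")
  if (anyDuplicated(names(dx)))
    fail("diagnoses", "duplicate diagnosis names")

  diagnoses <- list()
  for (dn in names(dx)) {
    p <- dx[[dn]]
    ppath <- paste0("diagnoses/", dn)
    if (is.null(p$root)) fail(ppath, "missing 'root'")
    if (is.null(p$nodes) || !length(p$nodes) || is.null(names(p$nodes)))
      fail(ppath, "missing or unnamed 'nodes'")
    nodes <- list()
    for (nid in names(p$nodes)) {
      nodes[[nid]] <- parse_node(p$nodes[[nid]], nid,
                                 paste0(ppath, "/nodes/", nid), fail)
    }
    root <- as.character(p$root)
    if (!root %in% names(nodes))
      fail(paste0(ppath, "/root"), sprintf("root '%s' is not a node", root))
    for (nid in names(nodes)) {
      miss <- setdiff(node_successors(nodes[[nid]]), names(nodes))
      if (length(miss))
        fail(paste0(ppath, "/nodes/", nid),
             sprintf("edge target '%s' is not a node", miss[[1L]]))
    }
    diagnoses[[dn]] <- structure(
      list(diagnosis = dn, root = root, nodes = nodes),
      class = "empirx_pathway")
  }

  dr <- x$dose_rules %||% list()
  dose_rules <- list()
  for (drug in names(dr)) {
    dose_rules[[drug]] <- parse_dose_table(dr[[drug]], drug,
                                           paste0("dose_rules/", drug), fail)
  }

  structure(list(version = as.character(x$version %||% "1"),
                 diagnoses = diagnoses,
                 dose_rules = dose_rules),
            class = "empirx_kb")
}

parse_node <- function(nd, nid, npath, fail) {
  kind <- nd$kind
  if (is.null(kind)) fail(npath, "missing 'kind'")
  if (identical(kind, "question")) {
    edges <- nd$edges
    if (is.null(edges) || !length(edges) || is.null(names(edges)))
      fail(npath, "question node needs named answer edges")
    list(id = nid, kind = "question",
         prompt = as.character(nd$prompt %||% nid),
         data_binding = if (!is.null(nd$data_binding)) as.character(nd$data_binding),
         edges = lapply(edges, as.character))
  } else if (identical(kind, "gate")) {
    nxt <- nd[["next"]]
    if (is.null(nxt)) fail(npath, "gate node needs 'next'")
    list(id = nid, kind = "gate",
         gate_kind = as.character(nd$gate_kind %||% "antibiogram_review"),
         window_days = as.integer(nd$window_days %||% 183L),
         next_node = as.character(nxt))
  } else if (identical(kind, "advice")) {
    if (isTRUE(nd$consult)) {
      list(id = nid, kind = "advice", consult = TRUE, regimen = NULL)
    } else if (!is.null(nd$regimen)) {
      list(id = nid, kind = "advice", consult = FALSE,
           regimen = parse_regimen(nd$regimen, paste0(npath, "/regimen"), fail))
    } else {
      fail(npath, "advice node needs a 'regimen' or 'consult: true'")
    }
  } else {
    fail(npath, sprintf("unknown node kind '%s'", as.character(kind)))
  }
}

parse_regimen <- function(r, rpath, fail) {
  if (is.null(r$drugs) || !length(r$drugs)) fail(rpath, "regimen needs drugs")
  drugs <- lapply(seq_along(r$drugs), function(i) {
    d <- r$drugs[[i]]
    if (is.null(d$drug)) fail(paste0(rpath, "/drugs[", i, "]"), "missing drug id")
    route <- as.character(d$route %||% "iv")
    if (!route %in% c("iv", "oral"))
      fail(paste0(rpath, "/drugs[", i, "]"), sprintf("route must be iv or oral, got '%s'", route))
    list(drug = as.character(d$drug), route = route)
  })
  duration <- as.numeric(unlist(r$duration_days %||% NA_real_))
  alts <- lapply(seq_along(r$alternatives %||% list()), function(i)
    parse_regimen(r$alternatives[[i]], paste0(rpath, "/alternatives[", i, "]"), fail))
  list(drugs = drugs, duration_days = duration,
       alternatives = alts, notes = as.character(r$notes %||% ""))
}

parse_dose_table <- function(tb, drug, tpath, fail) {
  rows <- tb$rows
  if (is.null(rows) || !length(rows)) fail(tpath, "dose table needs rows")
  parsed <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    lo <- as.numeric(r$egfr_min %||% fail(paste0(tpath, "/rows[", i, "]"), "missing egfr_min"))
    hi <- as.numeric(r$egfr_max %||% fail(paste0(tpath, "/rows[", i, "]"), "missing egfr_max"))
    consult <- isTRUE(r$consult)
    wb <- as.character(r$weight_basis %||% "none")
    if (!wb %in% c("none", "actual", "ideal"))
      fail(paste0(tpath, "/rows[", i, "]"), sprintf("bad weight_basis '%s'", wb))
    data.frame(egfr_lo = lo, egfr_hi = hi,
               weight_basis = wb,
               pregnancy_allowed = !isFALSE(r$pregnancy_allowed),
               consult = consult,
               dose_amount = as.numeric(r$dose %||% NA_real_),
               dose_unit = as.character(r$unit %||% NA_character_),
               interval_hours = as.numeric(r$interval_hours %||% NA_real_),
               stringsAsFactors = FALSE)
  })
  rows_df <- do.call(rbind, parsed)
  rows_df <- rows_df[order(rows_df$egfr_lo), , drop = FALSE]
  rownames(rows_df) <- NULL
  list(drug = drug, rows = rows_df,
       fallback = as.character(tb$fallback %||% "consult"))
}

node_successors <- function(nd) {
  switch(nd$kind,
         question = as.character(unlist(nd$edges, use.names = FALSE)),
         gate = nd$next_node,
         advice = character(0))
}

#' @export
print.empirx_kb <- function(x, ...) {
  cat("Guideline knowledge base (version ", x$version, ")\n", sep = "")
  cat("  diagnoses: ", paste(names(x$diagnoses), collapse = ", "), "\n", sep = "")
  cat("  dose tables: ", paste(names(x$dose_rules), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# All drugs referenced by a regimen, including its alternatives.
regimen_drugs <- function(reg, recursive = TRUE) {
  own <- vapply(reg$drugs, function(d) d$drug, character(1))
  if (recursive && length(reg$alternatives)) {
    own <- c(own, unlist(lapply(reg$alternatives, regimen_drugs)))
  }
  unique(own)
}

#' Validate a knowledge base
#'
#' Checks the semantic rules every usable knowledge base must satisfy:
#' no dangling edge targets, acyclicity, reachability of every node from the
#' pathway root, termination of every path in an advice node, at least two
#' distinct answers per question, a dose table for every advised drug
#' (including alternatives), and per-table eGFR band coverage of
#' \[0, Inf) without gaps or overlaps. Violations are returned as data,
#' not raised as errors, so a linter/CI can report them all at once.
#'
#' @param kb an `empirx_kb` object.
#' @return an `empirx_kb_validation` object: a list with `violations`
#'   (data frame with columns `rule`, `where`, `message`) and `is_valid`.
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "empirx_kb"))
  v <- list()
  add <- function(rule, where, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, where = where,
                                       message = message, stringsAsFactors = FALSE)

  for (dn in names(kb$diagnoses)) {
    pw <- kb$diagnoses[[dn]]
    ids <- names(pw$nodes)
    loc <- function(nid) paste0(dn, "/", nid)

    if (!pw$root %in% ids)
      add("dangling_root", dn, sprintf("root '%s' is not a node", pw$root))

    for (nid in ids) {
      nd <- pw$nodes[[nid]]
      miss <- setdiff(node_successors(nd), ids)
      for (m in miss)
        add("dangling_edge", loc(nid), sprintf("edge target '%s' does not exist", m))
      if (nd$kind == "question") {
        ans <- names(nd$edges)
        if (length(unique(ans)) < 2L)
          add("answer_edges", loc(nid),
              "question needs at least 2 edges with distinct answers")
      }
      if (nd$kind == "advice" && !nd$consult) {
        if (!length(nd$regimen$drugs)) {
          add("empty_regimen", loc(nid), "advice regimen has no drugs")
        } else {
          for (dg in regimen_drugs(nd$regimen)) {
            if (!dg %in% names(kb$dose_rules))
              add("missing_dose_table", loc(nid),
                  sprintf("drug '%s' has no dose rule table", dg))
          }
        }
      }
    }

    # Cycle detection: iterative DFS with colouring over existing edges.
    colour <- stats::setNames(rep(0L, length(ids)), ids) # 0 new, 1 open, 2 done
    cyclic <- FALSE
    visit <- function(nid) {
      stack <- list(list(id = nid, nxt = 1L))
      colour[nid] <<- 1L
      while (length(stack)) {
        top <- stack[[length(stack)]]
        succ <- intersect(node_successors(pw$nodes[[top$id]]), ids)
        if (top$nxt > length(succ)) {
          colour[top$id] <<- 2L
          stack[[length(stack)]] <- NULL
        } else {
          stack[[length(stack)]]$nxt <- top$nxt + 1L
          s <- succ[[top$nxt]]
          if (colour[s] == 1L) cyclic <<- TRUE
          else if (colour[s] == 0L) {
            colour[s] <<- 1L
            stack[[length(stack) + 1L]] <- list(id = s, nxt = 1L)
          }
        }
      }
    }
    for (nid in ids) if (colour[nid] == 0L) visit(nid)
    if (cyclic) add("cycle", dn, "pathway graph contains a cycle")

    # Reachability from root.
    if (pw$root %in% ids) {
      seen <- character(0)
      queue <- pw$root
      while (length(queue)) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        if (cur %in% seen) next
        seen <- c(seen, cur)
        queue <- c(queue, intersect(node_successors(pw$nodes[[cur]]), ids))
      }
      for (nid in setdiff(ids, seen))
        add("unreachable", loc(nid), "node is not reachable from the root")
      # Termination: every reachable sink must be an advice node.
      if (!cyclic) {
        for (nid in seen) {
          nd <- pw$nodes[[nid]]
          if (nd$kind != "advice" && !length(intersect(node_successors(nd), ids)))
            add("no_advice_terminal", loc(nid),
                sprintf("%s node has no valid successor; path does not end in advice", nd$kind))
        }
      }
    }
  }

  for (drug in names(kb$dose_rules)) {
    tb <- kb$dose_rules[[drug]]
    rows <- tb$rows
    if (!nrow(rows)) {
      add("band_coverage", drug, "dose table has no rows")
      next
    }
    if (rows$egfr_lo[1L] != 0)
      add("band_coverage", drug,
          sprintf("eGFR bands start at %g, not 0", rows$egfr_lo[1L]))
    if (is.finite(rows$egfr_hi[nrow(rows)]))
      add("band_coverage", drug, "eGFR bands do not extend to Inf")
    if (nrow(rows) > 1L) {
      for (i in seq_len(nrow(rows) - 1L)) {
        if (rows$egfr_hi[i] != rows$egfr_lo[i + 1L])
          add("band_coverage", drug,
              sprintf("gap or overlap between bands at eGFR %g/%g",
                      rows$egfr_hi[i], rows$egfr_lo[i + 1L]))
      }
    }
    if (any(rows$egfr_lo >= rows$egfr_hi))
      add("band_coverage", drug, "empty eGFR band (lo >= hi)")
    bad <- !rows$consult & (is.na(rows$dose_amount) | is.na(rows$dose_unit) |
                              is.na(rows$interval_hours))
    if (any(bad))
      add("incomplete_dose_row", drug,
          "non-consult row lacks dose, unit or interval")
  }

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), where = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(violations = violations, is_valid = nrow(violations) == 0L),
            class = "empirx_kb_validation")
}

#' @export
print.empirx_kb_validation <- function(x, ...) {
  if (x$is_valid) {
    cat("Knowledge base is valid (0 violations)\n")
  } else {
    cat("Knowledge base is INVALID:", nrow(x$violations), "violation(s)\n")
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s: %s\n", x$violations$rule[i],
                  x$violations$where[i], x$violations$message[i]))
  }
  invisible(x)
}

#' Enumerate all root-to-advice paths of a diagnosis pathway
#'
#' Exhaustive depth-first enumeration of every answer combination. Gates
#' contribute no answers. Used as the oracle for engine-equivalence checks
#' and by the synthetic cohort generator.
#'
#' @param kb an `empirx_kb` object (assumed validated; a cyclic pathway
#'   triggers a depth-guard error).
#' @param diagnosis diagnosis name present in `kb`.
#' @return a list of paths; each path is a list with `answers` (data frame
#'   with columns `node`, `answer`, in traversal order), `terminal`
#'   (advice node id) and `consult` (logical).
#' @export
enumerate_paths <- function(kb, diagnosis) {
  stopifnot(inherits(kb, "empirx_kb"))
  pw <- kb$diagnoses[[diagnosis]]
  if (is.null(pw))
    stop(sprintf("unknown diagnosis '%s'; available: %s", diagnosis,
                 paste(names(kb$diagnoses), collapse = ", ")))
  paths <- list()
  walk <- function(nid, answers, depth) {
    if (depth > 1000L) stop("pathway too deep; is the graph cyclic?")
    nd <- pw$nodes[[nid]]
    if (nd$kind == "advice") {
      paths[[length(paths) + 1L]] <<-
        list(answers = answers, terminal = nid, consult = nd$consult)
    } else if (nd$kind == "gate") {
      walk(nd$next_node, answers, depth + 1L)
    } else {
      for (a in names(nd$edges)) {
        walk(nd$edges[[a]],
             rbind(answers, data.frame(node = nid, answer = a,
                                       stringsAsFactors = FALSE)),
             depth + 1L)
      }
    }
  }
  walk(pw$root,
       data.frame(node = character(), answer = character(),
                  stringsAsFactors = FALSE), 1L)
  paths
}
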
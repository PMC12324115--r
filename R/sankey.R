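#' Build a step-indexed Sankey (alluvial) graph of the first K states
#'
#' Nodes are `(step, state)` pairs — the node at step `i`, state `s` counts
#' the patients whose `i`-th state is `s` — and links count patients with
#' that consecutive state pair.  States beyond `max_states` are dropped and
#' durations are ignored: time is not represented.  Each node stores a
#' `terminal_remainder`, the patients whose trajectory produces no outgoing
#' link from that node (still on the technique at the end of observation,
#' dead, or truncated at the depth limit), so that at every node
#' `count = outgoing links + terminal_remainder`.
#'
#' @inheritParams extract_transitions
#' @param max_states number of leading states kept (>= 2, default 4).
#' @return an object of class `sankey_graph`: list with `nodes`
#'   (data.frame `node`, `step`, `state`, `count`, `terminal_remainder`)
#'   and `links` (data.frame `source`, `target`, `step`, `from_state`,
#'   `to_state`, `count`); `source`/`target` index into `nodes$node`
#'   (0-based, the convention of common web Sankey renderers).
#' @examples
#' coh <- generate_cohort(cohort_config(50, seed = 2))
#' g <- build_sankey(classify_states(coh$sessions, coh$patients))
#' g$nodes
#' @export
build_sankey <- function(states, max_states = 4) {
  if (!is_count(max_states) || max_states < 2) {
    abort("`max_states` must be an integer >= 2")
  }
  empty_nodes <- data.frame(node = integer(), step = integer(),
                            state = character(), count = integer(),
                            terminal_remainder = integer(),
                            stringsAsFactors = FALSE)
  empty_links <- data.frame(source = integer(), target = integer(),
                            step = integer(), from_state = character(),
                            to_state = character(), count = integer(),
                            stringsAsFactors = FALSE)
  if (!is.data.frame(states) || nrow(states) == 0L) {
    return(structure(list(nodes = empty_nodes, links = empty_links),
                     class = "sankey_graph"))
  }
  labs <- lapply(state_labels(states), utils::head, n = max_states)

  node_keys <- unique(do.call(rbind, lapply(labs, function(s) {
    data.frame(step = seq_along(s), state = s, stringsAsFactors = FALSE)
  })))
  node_keys <- node_keys[order(node_keys$step,
                               match(node_keys$state, STATE_LEVELS)), ,
                         drop = FALSE]
  node_id <- stats::setNames(seq_len(nrow(node_keys)) - 1L,
                             paste(node_keys$step, node_keys$state))

  node_count <- integer(nrow(node_keys))
  link_tab <- list()
  for (s in labs) {
    for (i in seq_along(s)) {
      key <- paste(i, s[i])
      node_count[node_id[[key]] + 1L] <- node_count[node_id[[key]] + 1L] + 1L
    }
    if (length(s) > 1L) {
      for (i in seq_len(length(s) - 1L)) {
        lk <- paste(i, s[i], s[i + 1])
        link_tab[[lk]] <- (link_tab[[lk]] %||% 0L) + 1L
      }
    }
  }
  nodes <- cbind(node = seq_len(nrow(node_keys)) - 1L, node_keys,
                 count = node_count)
  rownames(nodes) <- NULL

  if (length(link_tab) > 0) {
    parts <- strsplit(names(link_tab), " ", fixed = TRUE)
    links <- data.frame(
      step = vapply(parts, function(p) as.integer(p[1]), integer(1)),
      from_state = vapply(parts, `[`, character(1), 2),
      to_state = vapply(parts, `[`, character(1), 3),
      count = unlist(link_tab, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    links$source <- node_id[paste(links$step, links$from_state)]
    links$target <- node_id[paste(links$step + 1L, links$to_state)]
    links <- links[order(links$source, links$target), ,
                   drop = FALSE]
    links <- links[, c("source", "target", "step", "from_state", "to_state",
                       "count")]
    rownames(links) <- NULL
  } else {
    links <- empty_links
  }
  outflow <- integer(nrow(nodes))
  if (nrow(links) > 0) {
    agg <- tapply(links$count, links$source, sum)
    outflow[as.integer(names(agg)) + 1L] <- as.integer(agg)
  }
  nodes$terminal_remainder <- nodes$count - outflow
  structure(list(nodes = nodes, links = links), class = "sankey_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sankey_graph <- function(x, ...) {
  cat(sprintf("Sankey graph: %d nodes over %d steps, %d links, %d patients\n",
              nrow(x$nodes),
              if (nrow(x$nodes)) max(x$nodes$step) else 0L,
              nrow(x$links),
              sum(x$nodes$count[x$nodes$step == 1L])))
  invisible(x)
}

#' Export a Sankey graph to JSON or a CSV edge list
#'
#' The JSON document holds a `nodes` array (`node`, `step`, `state`,
#' `count`, `terminal_remainder`) and a `links` array (`source`, `target`,
#' `value`) with 0-based node indices, the dialect consumed by common web
#' Sankey renderers.  The CSV edge list has columns
#' `step,from_state,to_state,count`.
#'
#' @param graph a `sankey_graph` from [build_sankey()].
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_sankey <- function(graph, path, format = c("json", "csv")) {
  if (!inherits(graph, "sankey_graph")) {
    abort("`graph` must be built with build_sankey()")
  }
  format <- match.arg(format)
  if (format == "json") {
    links <- graph$links[, c("source", "target", "count"), drop = FALSE]
    names(links)[3] <- "value"
    jsonlite::write_json(list(nodes = graph$nodes, links = links), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(graph$links[, c("step", "from_state", "to_state", "count"),
                                 drop = FALSE],
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back a JSON Sankey export
#'
#' @param path a file written by [export_sankey()] with `format = "json"`.
#' @return a `sankey_graph` object equal to the exported one.
#' @export
read_sankey <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  links <- as.data.frame(doc$links, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) {
    return(build_sankey(data.frame(patient_id = character(),
                                   state = character(), start_day = integer(),
                                   end_day = integer(), censored = logical())))
  }
  for (col in c("node", "step", "count", "terminal_remainder")) {
    nodes[[col]] <- as.integer(nodes[[col]])
  }
  if (nrow(links) > 0) {
    links$source <- as.integer(links$source)
    links$target <- as.integer(links$target)
    links$count <- as.integer(links$value)
    links$step <- nodes$step[links$source + 1L]
    links$from_state <- nodes$state[links$source + 1L]
    links$to_state <- nodes$state[links$target + 1L]
    links <- links[, c("source", "target", "step", "from_state", "to_state",
                       "count")]
  } else {
    links <- data.frame(source = integer(), target = integer(),
                        step = integer(), from_state = character(),
                        to_state = character(), count = integer(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, links = links), class = "sankey_graph")
}
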
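.resultTuples <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  tuples <- list()
  for (df in results) {
    snvCols <- grep("^SNV_", names(df))
    stat <- if ("ALPHA" %in% names(df) && !all(is.na(df$ALPHA)))
      df$ALPHA else df$BETA
    for (i in seq_len(nrow(df)))
      tuples[[length(tuples) + 1L]] <- list(
        ids = sort(unlist(df[i, snvCols], use.names = FALSE),
                   method = "radix"),
        stat = stat[i])
  }
  if (!length(tuples)) stop("no interaction results to plot")
  tuples
}

.sizeScale <- function(stat, sizeRange) {
  rng <- range(stat)
  if (diff(rng) == 0) return(rep(mean(sizeRange), length(stat)))
  sizeRange[1] + (stat - rng[1]) / diff(rng) * diff(sizeRange)
}

#' Build an interaction graph from search results
#'
#' Two graph modes mirror the two standard renderings of an interaction
#' list:
#' \describe{
#'   \item{pair}{SNVs are nodes; an m-SNV tuple becomes the clique of its
#'     C(m, 2) SNV pairs, each edge carrying the tuple's statistic.  Edges
#'     duplicated across tuples are merged keeping the maximum statistic.
#'     (Clique expansion of higher orders is a projection; it is flagged in
#'     the graph attribute \code{mode}.)}
#'   \item{bipartite}{each tuple of order >= 2 additionally becomes an
#'     interaction node connected to exactly its m member SNV nodes.}
#' }
#' Node size is a linear map of the node's statistic (for SNV nodes, the
#' maximum statistic over the tuples containing it) onto \code{sizeRange}.
#'
#' @param results a per-order data.frame from [exhaustiveSearch()], or a
#'   list of them.
#' @param annotations optional data.frame of per-SNV attributes; the first
#'   column must hold SNV ids.  SNVs missing from the table keep empty
#'   attributes (with a warning).
#' @param mode \code{"pair"} or \code{"bipartite"}.
#' @param sizeRange numeric length-2: node sizes mapped onto this interval.
#' @return an \pkg{igraph} graph with vertex attributes \code{type}
#'   (\code{snv}/\code{interaction}), \code{stat}, \code{size}, and edge
#'   attribute \code{stat}.
#' @export
buildInteractionGraph <- function(results, annotations = NULL,
                                  mode = c("pair", "bipartite"),
                                  sizeRange = c(10, 50)) {
  mode <- match.arg(mode)
  tuples <- .resultTuples(results)

  snvStat <- list()
  for (tp in tuples)
    for (id in tp$ids)
      snvStat[[id]] <- max(snvStat[[id]] %||% -Inf, tp$stat)
  snvIds <- sort(names(snvStat), method = "radix")
  nodes <- data.frame(name = snvIds, type = "snv",
                      stat = unlist(snvStat[snvIds]),
                      stringsAsFactors = FALSE)

  edges <- NULL
  if (mode == "pair") {
    ee <- list()
    for (tp in tuples) {
      if (length(tp$ids) < 2L) next
      prs <- utils::combn(tp$ids, 2L)
      for (j in seq_len(ncol(prs))) {
        key <- paste(prs[, j], collapse = "\r")
        ee[[key]] <- max(ee[[key]] %||% -Inf, tp$stat)
      }
    }
    if (length(ee)) {
      fromTo <- do.call(rbind, strsplit(names(ee), "\r", fixed = TRUE))
      edges <- data.frame(from = fromTo[, 1], to = fromTo[, 2],
                          stat = unlist(ee), stringsAsFactors = FALSE)
    }
  } else {
    iNodes <- list(); ee <- list()
    for (tp in tuples) {
      if (length(tp$ids) < 2L) next
      iname <- paste(tp$ids, collapse = "+")
      iNodes[[iname]] <- max(iNodes[[iname]] %||% -Inf, tp$stat)
      for (id in tp$ids)
        ee[[paste(iname, id, sep = "\r")]] <- tp$stat
    }
    if (length(iNodes))
      nodes <- rbind(nodes,
                     data.frame(name = names(iNodes), type = "interaction",
                                stat = unlist(iNodes),
                                stringsAsFactors = FALSE))
    if (length(ee)) {
      fromTo <- do.call(rbind, strsplit(names(ee), "\r", fixed = TRUE))
      edges <- data.frame(from = fromTo[, 1], to = fromTo[, 2],
                          stat = unlist(ee), stringsAsFactors = FALSE)
    }
  }
  nodes$size <- .sizeScale(nodes$stat, sizeRange)

  if (!is.null(annotations)) {
    key <- as.character(annotations[[1]])
    missing <- setdiff(snvIds, key)
    if (length(missing))
      warning("no annotation for SNV(s): ",
              paste(head(missing, 5), collapse = ", "))
    hit <- match(nodes$name, key)
    for (col in names(annotations)[-1]) {
      v <- annotations[[col]][hit]
      nodes[[col]] <- v
    }
  }

  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(0),
                                       to = character(0),
                                       stat = numeric(0)) else edges,
    directed = FALSE, vertices = nodes)
  g <- igraph::set_graph_attr(g, "mode", mode)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an interaction graph to file
#'
#' @param graph an \pkg{igraph} graph from [buildInteractionGraph()].
#' @param path output path.
#' @param format \code{"graphml"} (attributes embedded), \code{"sif"}
#'   (simple interaction format; node/edge attributes are written to a
#'   \code{<path>.attrs.tsv} sidecar with a warning), or
#'   \code{"cytoscape"} (Cytoscape JSON).
#' @return invisibly, \code{path}.
#' @export
writeInteractionGraph <- function(graph, path,
                                  format = c("graphml", "sif", "cytoscape")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "sif") {
    el <- igraph::as_edgelist(graph)
    lines <- if (nrow(el)) paste(el[, 1], "interacts", el[, 2]) else character(0)
    isolated <- setdiff(igraph::V(graph)$name, as.vector(el))
    writeLines(c(lines, isolated), path)
    attrs <- data.frame(name = igraph::V(graph)$name,
                        type = igraph::V(graph)$type,
                        stat = igraph::V(graph)$stat,
                        size = igraph::V(graph)$size)
    sidecar <- paste0(path, ".attrs.tsv")
    write.table(attrs, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
    warning("SIF cannot carry attributes; node attributes written to ",
            sidecar)
  } else {
    v <- igraph::V(graph)
    nodes <- lapply(seq_along(v), function(i) {
      data <- list(id = v$name[i], type = v$type[i], stat = v$stat[i],
                   size = v$size[i])
      list(data = data)
    })
    el <- igraph::as_edgelist(graph)
    es <- igraph::E(graph)
    edges <- lapply(seq_len(nrow(el)), function(i)
      list(data = list(id = paste0("e", i), source = el[i, 1],
                       target = el[i, 2], stat = es$stat[i])))
    jsonlite::write_json(list(elements = list(nodes = nodes, edges = edges)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
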
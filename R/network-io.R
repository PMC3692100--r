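#' Export a coevolution network
#'
#' Three formats: \code{sif} (Cytoscape simple interaction format, one
#' \code{id1 coevolves id2} line per edge plus bare lines for isolated
#' nodes), \code{graphml} (score, p-value and q-value carried as edge
#' attributes, annotations as node attributes) and \code{tsv} (columns
#' id1, id2, score, pvalue, qvalue; header-only when the network is empty).
#'
#' @param net a \code{coevolution_network}.
#' @param path output file path.
#' @param format \code{"sif"}, \code{"graphml"} or \code{"tsv"}.
#' @return the path, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "coevolution_network"))
  if (format == "sif") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (nrow(net$edges)) {
      writeLines(paste(net$edges$id1, "coevolves", net$edges$id2),
                 con, sep = "\n")
    }
    isolated <- setdiff(net$nodes$id, c(net$edges$id1, net$edges$id2))
    if (length(isolated)) writeLines(isolated, con, sep = "\n")
  } else if (format == "graphml") {
    g <- network_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    df <- net$edges[, c("id1", "id2", "score", "pvalue", "qvalue"),
                    drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
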
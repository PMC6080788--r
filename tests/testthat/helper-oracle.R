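# Independent LP brute-force hull oracle (scipy HiGHS via python).
# Returns, per cloud, 1-based vertex indices and a 2-column edge matrix.
lp_hull_oracle <- function(clouds) {
  if (is.matrix(clouds)) clouds <- list(clouds)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(clouds = lapply(clouds, unname)),
                              digits = NA), infile)
  status <- system2("python", c(test_path("oracle_hull.py"), infile, outfile),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("LP oracle failed: ", paste(status, collapse = "\n"))
  res <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
  lapply(res, function(r) {
    edges <- do.call(rbind, lapply(r$edges, unlist))
    if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
    list(vertices = sort(unlist(r$vertices)), edges = edges)
  })
}

# canonical form of an edge set for comparison: sorted "a-b" strings
edge_key <- function(edges) {
  if (length(edges) == 0) return(character(0))
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
             sep = "-"))
}
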
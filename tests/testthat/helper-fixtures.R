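# Shared fixtures built in code (no files shipped).

# A tiny deterministic two-group dataset with known group means.
toyDataset <- function() {
    values <- rbind(
        feat1 = c(1, 3, 3, 5),    # meanA = 2, meanB = 4
        feat2 = c(0, 0, 0, 0),    # all zero
        feat3 = c(1, 2, 4, 8))
    colnames(values) <- c("s1", "s2", "s3", "s4")
    TwoGroupExperiment(values, group = c("A", "A", "B", "B"))
}

# Write a matrix file in the package's tab-delimited layout.
writeToyMatrixFile <- function(path, values, sampleIds, featureIds,
                               groupLine = NULL) {
    lines <- paste(c("feature_id", sampleIds), collapse = "\t")
    if (!is.null(groupLine))
        lines <- c(lines, paste(c("group", groupLine), collapse = "\t"))
    lines <- c(lines, vapply(seq_len(nrow(values)), function(i)
        paste(c(featureIds[i], format(values[i, ], digits = 17)),
              collapse = "\t"), character(1)))
    writeLines(lines, path)
    path
}

# Random p-value vectors with a mix of uniform and small-signal shapes.
randomPvalues <- function(m, signal = runif(1) < 0.5) {
    p <- runif(m)
    if (signal) {
        k <- sample.int(max(1, m %/% 4), 1)
        p[seq_len(k)] <- rbeta(k, 0.3, 6)
    }
    p
}
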
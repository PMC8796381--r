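# Shared task pool for all analyses. Each task is an independent pure
# function of serializable inputs, so results are a deterministic function of
# the task list: fork-based workers only change wall time, never values or
# ordering. Falls back to sequential execution when forking is unavailable
# (e.g. on Windows) or workers == 1.
fs_lapply <- function(X, FUN, workers = 1L) {
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || length(X) <= 1L ||
      .Platform$OS.type == "windows") {
    return(lapply(X, FUN))
  }
  res <- parallel::mclapply(X, FUN, mc.cores = workers,
                            mc.preschedule = TRUE, mc.set.seed = FALSE)
  # re-raise worker errors in the parent so strict callers abort as if serial
  for (r in res) {
    if (inherits(r, "try-error")) {
      stop(attr(r, "condition") %||%
             simpleError("worker task failed"), call. = FALSE)
    }
  }
  res
}
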
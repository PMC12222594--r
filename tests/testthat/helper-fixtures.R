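# Shared fixture builders; everything is generated in code at test time.

tinyRecording <- function(data, fs = 256, channels = NULL) {
  channels <- channels %||% sprintf("E%02d", seq_len(nrow(data)))
  new("ContinuousRecording", data = data, fs = fs, channels = channels,
      reference = "raw")
}

tinyEnvelope <- function(values, fs = 256, sourceId = "test") {
  new("OnsetEnvelope", values = values, fs = fs, sourceId = sourceId,
      pooledSigma = NA_real_,
      pulses = data.frame(timeS = numeric(0), amplitude = numeric(0)))
}

# small cohort for integration-style unit tests
tinySpec <- function(seed = 5, ...) {
  cohortSpec(nSubjects = 1, nTrials = 4, trialDurationS = 20, nChannels = 4,
             seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
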
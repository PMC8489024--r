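# minimal constant-layout pupil trace for analysis tests
mk_trace <- function(area, fps = 30, blink_prob = rep(0, length(area))) {
  n <- length(area)
  as_pupil_trace(data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / fps,
                            area_px = area, pupil_x = 0, pupil_y = 0,
                            eye_prob = 1, blink_prob = blink_prob,
                            trig1 = FALSE, trig2 = FALSE, trig3 = FALSE,
                            trig4 = FALSE), fps)
}
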
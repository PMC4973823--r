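id,ind01,ind02,ind03,ind04,ind05,ind06,ind07,ind08,ind09,ind10,ind11,ind12,ind13,ind14,ind15,ind16,ind17,ind18,ind19,ind20,ind21,ind22,ind23,ind24
ind01,0,0.133333333333333,0.183333333333333,0.216666666666667,0.166666666666667,0.166666666666667,0.116666666666667,0.15,0.183333333333333,0.2,0.166666666666667,0.15,0,0,0,0,0,0,0,0,0,0,0,0
ind02,0.133333333333333,0,0.233333333333333,0.316666666666667,0.216666666666667,0.266666666666667,0.15,0.1,0.216666666666667,0.183333333333333,0.2,0.183333333333333,0,0,0,0,0,0,0,0,0,0,0,0
ind03,0.183333333333333,0.233333333333333,0,0.366666666666667,0.35,0.333333333333333,0.35,0.166666666666667,0.266666666666667,0.3,0.266666666666667,0.25,0,0,0,0,0,0,0,0,0,0,0,0
ind04,0.216666666666667,0.316666666666667,0.366666666666667,0,0.333333333333333,0.316666666666667,0.333333333333333,0.133333333333333,0.283333333333333,0.266666666666667,0.35,0.366666666666667,0,0,0,0,0,0,0,0,0,0,0,0
ind05,0.166666666666667,0.216666666666667,0.35,0.333333333333333,0,0.25,0.233333333333333,0.0833333333333333,0.266666666666667,0.216666666666667,0.216666666666667,0.216666666666667,0,0,0,0,0,0,0,0,0,0,0,0
ind06,0.166666666666667,0.266666666666667,0.333333333333333,0.316666666666667,0.25,0,0.333333333333333,0.266666666666667,0.2,0.266666666666667,0.25,0.25,0,0,0,0,0,0,0,0,0,0,0,0
ind07,0.116666666666667,0.15,0.35,0.333333333333333,0.233333333333333,0.333333333333333,0,0.166666666666667,0.216666666666667,0.25,0.216666666666667,0.233333333333333,0,0,0,0,0,0,0,0,0,0,0,0
ind08,0.15,0.1,0.166666666666667,0.133333333333333,0.0833333333333333,0.266666666666667,0.166666666666667,0,0.05,0.133333333333333,0.183333333333333,0.15,0,0,0,0,0,0,0,0,0,0,0,0
ind09,0.183333333333333,0.216666666666667,0.266666666666667,0.283333333333333,0.266666666666667,0.2,0.216666666666667,0.05,0,0.233333333333333,0.183333333333333,0.15,0,0,0,0,0,0,0,0,0,0,0,0
ind10,0.2,0.183333333333333,0.3,0.266666666666667,0.216666666666667,0.266666666666667,0.25,0.133333333333333,0.233333333333333,0,0.2,0.166666666666667,0,0,0,0,0,0,0,0,0,0,0,0
ind11,0.166666666666667,0.2,0.266666666666667,0.35,0.216666666666667,0.25,0.216666666666667,0.183333333333333,0.183333333333333,0.2,0,0.216666666666667,0,0,0,0,0,0,0,0,0,0,0,0
ind12,0.15,0.183333333333333,0.25,0.366666666666667,0.216666666666667,0.25,0.233333333333333,0.15,0.15,0.166666666666667,0.216666666666667,0,0,0,0,0,0,0,0,0,0,0,0,0
ind13,0,0,0,0,0,0,0,0,0,0,0,0,0,0.2,0.233333333333333,0.266666666666667,0.233333333333333,0.166666666666667,0.25,0.166666666666667,0.183333333333333,0.183333333333333,0.266666666666667,0.183333333333333
ind14,0,0,0,0,0,0,0,0,0,0,0,0,0.2,0,0.2,0.233333333333333,0.166666666666667,0.166666666666667,0.183333333333333,0.183333333333333,0.266666666666667,0.25,0.283333333333333,0.25
ind15,0,0,0,0,0,0,0,0,0,0,0,0,0.233333333333333,0.2,0,0.383333333333333,0.233333333333333,0.25,0.25,0.283333333333333,0.25,0.216666666666667,0.316666666666667,0.283333333333333
ind16,0,0,0,0,0,0,0,0,0,0,0,0,0.266666666666667,0.233333333333333,0.383333333333333,0,0.283333333333333,0.133333333333333,0.233333333333333,0.233333333333333,0.233333333333333,0.216666666666667,0.3,0.233333333333333
ind17,0,0,0,0,0,0,0,0,0,0,0,0,0.233333333333333,0.166666666666667,0.233333333333333,0.283333333333333,0,0.133333333333333,0.2,0.25,0.166666666666667,0.166666666666667,0.333333333333333,0.233333333333333
ind18,0,0,0,0,0,0,0,0,0,0,0,0,0.166666666666667,0.166666666666667,0.25,0.133333333333333,0.133333333333333,0,0.15,0.166666666666667,0.1,0.15,0.183333333333333,0.133333333333333
ind19,0,0,0,0,0,0,0,0,0,0,0,0,0.25,0.183333333333333,0.25,0.233333333333333,0.2,0.15,0,0.15,0.25,0.216666666666667,0.266666666666667,0.183333333333333
ind20,0,0,0,0,0,0,0,0,0,0,0,0,0.166666666666667,0.183333333333333,0.283333333333333,0.233333333333333,0.25,0.166666666666667,0.15,0,0.216666666666667,0.183333333333333,0.216666666666667,0.133333333333333
ind21,0,0,0,0,0,0,0,0,0,0,0,0,0.183333333333333,0.266666666666667,0.25,0.233333333333333,0.166666666666667,0.1,0.25,0.216666666666667,0,0.183333333333333,0.233333333333333,0.233333333333333
ind22,0,0,0,0,0,0,0,0,0,0,0,0,0.183333333333333,0.25,0.216666666666667,0.216666666666667,0.166666666666667,0.15,0.216666666666667,0.183333333333333,0.183333333333333,0,0.3,0.233333333333333
ind23,0,0,0,0,0,0,0,0,0,0,0,0,0.266666666666667,0.283333333333333,0.316666666666667,0.3,0.333333333333333,0.183333333333333,0.266666666666667,0.216666666666667,0.233333333333333,0.3,0,0.316666666666667
ind24,0,0,0,0,0,0,0,0,0,0,0,0,0.183333333333333,0.25,0.283333333333333,0.233333333333333,0.233333333333333,0.133333333333333,0.183333333333333,0.133333333333333,0.233333333333333,0.233333333333333,0.316666666666667,0
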
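[
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  },
  {
    "outcome": "correct",
    "reading_time_s": 5,
    "latency_s": 10
  }
]
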
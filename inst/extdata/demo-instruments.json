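{
  "ratings": {
    "mental": 30,
    "physical": 10,
    "temporal": 25,
    "performance": 15,
    "effort": 30,
    "frustration": 10
  },
  "pair_choices": [
    {
      "a": "mental",
      "b": "physical",
      "winner": "mental"
    },
    {
      "a": "mental",
      "b": "temporal",
      "winner": "mental"
    },
    {
      "a": "mental",
      "b": "performance",
      "winner": "mental"
    },
    {
      "a": "mental",
      "b": "effort",
      "winner": "mental"
    },
    {
      "a": "mental",
      "b": "frustration",
      "winner": "mental"
    },
    {
      "a": "physical",
      "b": "temporal",
      "winner": "physical"
    },
    {
      "a": "physical",
      "b": "performance",
      "winner": "physical"
    },
    {
      "a": "physical",
      "b": "effort",
      "winner": "physical"
    },
    {
      "a": "physical",
      "b": "frustration",
      "winner": "physical"
    },
    {
      "a": "temporal",
      "b": "performance",
      "winner": "temporal"
    },
    {
      "a": "temporal",
      "b": "effort",
      "winner": "temporal"
    },
    {
      "a": "temporal",
      "b": "frustration",
      "winner": "temporal"
    },
    {
      "a": "performance",
      "b": "effort",
      "winner": "performance"
    },
    {
      "a": "performance",
      "b": "frustration",
      "winner": "performance"
    },
    {
      "a": "effort",
      "b": "frustration",
      "winner": "effort"
    }
  ],
  "posttask": 6
}
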
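{
  "schema_version": 1,
  "bank_id": "builtin-text",
  "modality": "text",
  "items": [
    {
      "item_id": "text-01",
      "modality": "text",
      "info_payload": "The marathon race covers just over forty-two kilometers",
      "question_prompt": "How many kilometers does a marathon cover?",
      "choices": ["Forty-two", "Twenty-six", "Fifty", "Thirty"],
      "correct_index": 0,
      "order_rank": 1
    },
    {
      "item_id": "text-02",
      "modality": "text",
      "info_payload": "The Great Wall was built in ancient China",
      "question_prompt": "Where was the Great Wall built?",
      "choices": ["Japan", "China", "India", "Egypt"],
      "correct_index": 1,
      "order_rank": 2
    },
    {
      "item_id": "text-03",
      "modality": "text",
      "info_payload": "The river Nile flows through the country Egypt",
      "question_prompt": "Which country does the Nile flow through?",
      "choices": ["Kenya", "Morocco", "Egypt", "Sudan"],
      "correct_index": 2,
      "order_rank": 3
    },
    {
      "item_id": "text-04",
      "modality": "text",
      "info_payload": "The movie Casablanca was filmed in black and white",
      "question_prompt": "How was Casablanca filmed?",
      "choices": ["In color", "Animated", "Silent", "Black and white"],
      "correct_index": 3,
      "order_rank": 4
    },
    {
      "item_id": "text-05",
      "modality": "text",
      "info_payload": "A football team fields eleven players at once",
      "question_prompt": "How many players does a football team field?",
      "choices": ["Eleven", "Nine", "Seven", "Fifteen"],
      "correct_index": 0,
      "order_rank": 5
    },
    {
      "item_id": "text-06",
      "modality": "text",
      "info_payload": "The pyramids of Giza stand near the city Cairo",
      "question_prompt": "Which city is near the pyramids of Giza?",
      "choices": ["Luxor", "Cairo", "Alexandria", "Amman"],
      "correct_index": 1,
      "order_rank": 6
    },
    {
      "item_id": "text-07",
      "modality": "text",
      "info_payload": "Mount Everest is the highest mountain on Earth",
      "question_prompt": "Which mountain is the highest on Earth?",
      "choices": ["K2", "Kilimanjaro", "Everest", "Mont Blanc"],
      "correct_index": 2,
      "order_rank": 7
    },
    {
      "item_id": "text-08",
      "modality": "text",
      "info_payload": "The Olympic games happen once every four years",
      "question_prompt": "How often do the Olympic games happen?",
      "choices": ["Every year", "Every two years", "Every five years", "Every four years"],
      "correct_index": 3,
      "order_rank": 8
    },
    {
      "item_id": "text-09",
      "modality": "text",
      "info_payload": "The Titanic sank on its very first voyage",
      "question_prompt": "On which voyage did the Titanic sink?",
      "choices": ["Its first", "Its second", "Its fifth", "Its last"],
      "correct_index": 0,
      "order_rank": 9
    },
    {
      "item_id": "text-10",
      "modality": "text",
      "info_payload": "Tennis matches at Wimbledon are played on grass",
      "question_prompt": "What surface is used at Wimbledon?",
      "choices": ["Clay", "Grass", "Concrete", "Carpet"],
      "correct_index": 1,
      "order_rank": 10
    }
  ]
}
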
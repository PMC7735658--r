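{
  "pain": [
    "pain", "pains", "painful", "ache", "aches", "aching", "achy", "achey",
    "hurt", "hurts", "hurting", "sore", "soreness", "cramp", "cramps",
    "cramping", "crampy", "throbbing", "stabbing", "tender", "tenderness",
    "backache", "headache", "headaches", "ouch", "agony"
  ],
  "sleep_and_fatigue": [
    "sleep", "sleeping", "sleepless", "insomnia", "tired", "tiredness",
    "fatigue", "fatigued", "exhausted", "exhaustion", "nap", "naps",
    "napping", "drowsy", "restless", "weary", "energy", "listless",
    "sleepy", "wiped out"
  ],
  "hormones_and_emotions": [
    "hormone", "hormones", "hormonal", "estrogen", "hrt", "mood", "moods",
    "moody", "weepy", "weepies", "crying", "cried", "tearful", "tears",
    "depressed", "depression", "anxiety", "anxious", "emotional", "emotions",
    "irritable", "hot flashes", "hot flash", "flashes", "menopause",
    "menopausal", "sad"
  ],
  "digestion": [
    "gastritis", "constipation", "constipated", "bloat", "bloated",
    "bloating", "gas", "gassy", "nausea", "nauseous", "vomit", "vomiting",
    "vomitting", "diarrhea", "diarrhoea", "bowel", "bowels", "indigestion",
    "heartburn", "stomach", "tummy", "appetite", "reflux"
  ],
  "swelling": [
    "swelling", "swollen", "swell", "swells", "swelly", "swellybelly",
    "swelly belly", "puffy", "puffiness", "inflamed", "inflammation",
    "distended", "distension", "edema", "oedema"
  ],
  "bleeding": [
    "bleeding", "bleed", "bleeds", "bled", "blood", "bloody", "spotting",
    "spotty", "discharge", "hemorrhage", "haemorrhage", "clot", "clots",
    "clotting", "period", "staining", "oozing", "gush", "gushing"
  ],
  "urination": [
    "urine", "urinate", "urinating", "urination", "urinary", "uti",
    "bladder", "pee", "peeing", "peed", "incontinence", "incontinent",
    "leaking", "leakage", "void", "voiding", "urgency", "retention",
    "kidney"
  ],
  "intimacy": [
    "sex", "sexy", "sexual", "sexually", "intimacy", "intimate",
    "intercourse", "libido", "orgasm", "dryness", "lubricant",
    "lubrication", "dyspareunia", "arousal", "romance", "celibate"
  ],
  "odd_sensations": [
    "itch", "itches", "itchy", "itching", "burn", "burns", "burning",
    "tingling", "tingle", "tingles", "numb", "numbness", "twinge",
    "twinges", "prickly", "zings", "zingers", "pulling", "tugging",
    "crawling", "buzzing", "shooting"
  ],
  "drugs": [
    "medication", "medications", "meds", "drug", "drugs", "pill", "pills",
    "percocet", "vicodin", "oxycodone", "ibuprofen", "advil", "tylenol",
    "motrin", "naproxen", "narcotic", "narcotics", "morphine", "codeine",
    "antibiotic", "antibiotics", "painkiller", "painkillers", "dosage",
    "dose", "tramadol"
  ],
  "fever_and_infection": [
    "fever", "fevers", "feverish", "temperature", "temp", "infection",
    "infections", "infected", "chills", "pus", "abscess", "cellulitis",
    "sepsis", "septic", "inflammed"
  ],
  "family": [
    "family", "husband", "hubby", "wife", "kids", "children", "child",
    "daughter", "son", "mom", "mother", "sister", "grandkids", "toddler",
    "baby", "babies", "spouse", "partner", "grandchildren"
  ]
}
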
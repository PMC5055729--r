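# Default keyword groups: each entry maps a primary keyword to its aliases.
# The symptom list covers the 46 infectious-disease-related symptom groups of
# the surveillance configuration; the emotion list covers the six basic
# emotions (with "happy" split out of "joy" into its own group, since it is
# dominated by birthday greetings and calendar events). Aliases are curated
# synonyms and common colloquial variants.
symptom:
  headache: [migraine, head ache, splitting headache, pounding head]
  vomit: [throwing up, being sick, puking, puke, vomiting, threw up, throw up]
  hayfever: [hay fever, pollen allergy]
  sore throat: [throat hurts, scratchy throat, painful throat]
  pain: [aching, in agony, agonising]
  malaise: [run down, under the weather, feeling rough]
  flu: [influenza, the flu, flu jab]
  cough: [coughing, hacking cough, chesty cough]
  tonsillitis: [tonsilitis, swollen tonsils]
  common cold: [head cold, caught a cold, the sniffles]
  infection: [infected, infectious]
  abdominal pain: [stomach ache, tummy ache, stomach cramps, belly ache]
  sneeze: [sneezing, sneezes]
  asthma: [asthma attack, inhaler, wheezy, wheezing]
  shortness of breath: [short of breath, breathless, "can't breathe", can’t breathe]
  earache: [ear ache, ear hurts]
  nasal congestion: [blocked nose, stuffy nose, bunged up]
  tremor: [trembling, shaking, the shakes]
  itch: [itching, itchy, scratching]
  anxiety: [anxious, panic attack, panicking]
  fever: [high temperature, feverish, burning up]
  nosebleed: [nose bleed, bleeding nose]
  faint: [fainted, fainting, passed out, blacked out]
  skin rash: [rash, hives, come out in spots]
  cramp: [cramps, cramping]
  diarrhea: [diarrhoea, the runs, upset stomach]
  chest pain: [chest hurts, tight chest]
  swollen gland: [swollen glands, glands are up]
  conjunctivitis: [pink eye, eye infection]
  stinging sensation: [stinging, stings]
  bleeding: [bleed, blood loss]
  chickenpox: [chicken pox, varicella]
  runny nose: [nose is running, streaming nose]
  swelling: [swollen, puffed up]
  meningitis: [meningococcal]
  pneumonia: [chest infection]
  seizure: [seizures, fit, convulsion]
  constipation: [constipated, bunged]
  palpitation: [palpitations, heart racing]
  norovirus: [winter vomiting bug, stomach bug]
  neck pain: [stiff neck, neck hurts]
  scarlet fever: [scarlatina]
  dehydration: [dehydrated]
  dysentery: []
  tearing: [watery eyes, eyes watering]
  dry mouth: [mouth is dry, parched mouth]
emotion:
  love: [adore, adored, adoring, loving, affection, fondness, cherish]
  joy: [glad, delighted, pleased, joyful, cheerful, elated, ecstatic, thrilled, jubilant]
  happy: [happiness, happier, happiest]
  surprise: [amazed, astonished, surprised, astounded, amazement, astonishment]
  sadness: [depressed, unhappy, crying, sad, sorrow, grief, gloomy, miserable, heartbroken]
  anger: [angry, furious, outraged, enraged, irritated, annoyed, fuming, raging]
  fear: [afraid, scared, terrified, frightened, panicked, petrified, fearful]
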